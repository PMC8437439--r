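#' Read a ramp current at a stated voltage
#'
#' Averages the samples whose ramp voltage lies within `window_mV` of `v`
#' (the standard readouts are -160 mV for calcium and manganese currents,
#' -80 mV for sodium, +80 mV for the outward check). The first and last 2 ms
#' of the sweep are excluded to stay clear of capacitance transients at the
#' protocol edges. Falls back to linear interpolation if the window is empty.
#'
#' @param sweep A [ramp_sweep()].
#' @param v Voltage in mV; must lie within the protocol range.
#' @param window_mV Half-width of the averaging window.
#' @param edge_ms Time excluded at each protocol edge.
#' @return A list with `current_pA` and `density_pA_pF` (current divided by
#'   capacitance; inward negative).
#' @export
current_at_voltage <- function(sweep, v, window_mV = 2, edge_ms = 2) {
  stopifnot(inherits(sweep, "ramp_sweep"))
  rng <- range(sweep$voltage)
  if (v < rng[1] || v > rng[2]) stop("voltage outside the protocol range")
  keep <- sweep$time >= min(sweep$time) + edge_ms / 1000 &
    sweep$time <= max(sweep$time) - edge_ms / 1000
  vv <- sweep$voltage[keep]
  ii <- sweep$current[keep]
  sel <- abs(vv - v) <= window_mV
  i <- if (any(sel)) mean(ii[sel]) else approx(vv, ii, xout = v, ties = mean)$y
  list(current_pA = i, density_pA_pF = i / sweep$capacitance)
}

#' Subtract a control sweep from a test sweep
#'
#' Pointwise difference after checking that the two sweeps follow the same
#' voltage protocol. Used to remove leak/background current recorded in
#' divalent-free control solution.
#'
#' @param sweep,control [ramp_sweep()] objects with matching protocols.
#' @return A `ramp_sweep` with the difference current.
#' @export
subtract_control <- function(sweep, control) {
  stopifnot(inherits(sweep, "ramp_sweep"), inherits(control, "ramp_sweep"))
  if (length(sweep$voltage) != length(control$voltage) ||
      max(abs(sweep$voltage - control$voltage)) > 1e-6)
    stop("sweeps follow different voltage protocols")
  out <- sweep
  out$current <- sweep$current - control$current
  out
}

#' Ratio of currents measured in the same mitoplast
#'
#' Same-mitoplast ratios (calcium over sodium current, manganese over
#' calcium) cancel channel-number and size differences; the estimator is
#' invariant to a common gain on both sweeps.
#'
#' @param i_a,i_b Currents (pA or pA/pF) from the same mitoplast; vectors are
#'   paired elementwise.
#' @return `i_a / i_b`.
#' @export
paired_ratio <- function(i_a, i_b) {
  if (length(i_a) != length(i_b)) stop("paired ratios need equal-length inputs")
  i_a / i_b
}

#' Fit a Hill inhibition curve to a magnesium block dose-response
#'
#' Least-squares fit of `f(c) = 1 / (1 + (c/IC50)^nH)` to currents
#' normalized to the zero-magnesium level; `f(0) = 1` is fixed rather than a
#' free parameter, matching the normalization. Five seeded starting points
#' guard against local minima.
#'
#' @param conc Inhibitor concentrations in uM (must include 0 and at least 4
#'   levels).
#' @param response Currents normalized to the response at zero inhibitor.
#' @param seed Seed for the multi-start perturbations.
#' @return A list of class `hill_fit`: `ic50`, `n_h`, standard errors, the
#'   residual norm, and a `non_monotone` warning flag.
#' @export
fit_hill_inhibition <- function(conc, response, seed = 1) {
  stopifnot(length(conc) == length(response))
  if (length(unique(conc)) < 4 || !any(conc == 0))
    stop("need at least 4 concentrations including 0")
  ok <- conc > 0
  non_monotone <- FALSE
  sm <- tapply(response[ok], conc[ok], mean)
  if (any(diff(sm[order(as.numeric(names(sm)))]) > 0.1)) {
    non_monotone <- TRUE
    warning("dose-response is non-monotone beyond noise tolerance")
  }
  ic50_0 <- conc[ok][which.min(abs(response[ok] - 0.5))]
  if (!is.finite(ic50_0) || ic50_0 <= 0) ic50_0 <- median(conc[ok])
  if (!is.null(seed)) set.seed(seed)
  starts <- rbind(c(ic50_0, 1),
                  cbind(ic50_0 * exp(rnorm(4, 0, 0.7)), exp(rnorm(4, 0, 0.3))))
  df <- data.frame(conc = conc, response = response)
  best <- NULL
  for (s in seq_len(nrow(starts))) {
    fit <- tryCatch(
      minpack.lm::nlsLM(response ~ 1 / (1 + (conc / ic50)^n_h), data = df,
                        start = list(ic50 = starts[s, 1], n_h = starts[s, 2]),
                        lower = c(1e-9, 1e-3),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit) &&
        (is.null(best) || deviance(fit) < deviance(best))) best <- fit
  }
  if (is.null(best)) stop("Hill fit failed from all starting points")
  est <- coef(best)
  se <- tryCatch(sqrt(diag(vcov(best))), error = function(e) rep(NA_real_, 2))
  structure(list(ic50 = unname(est["ic50"]), n_h = unname(est["n_h"]),
                 ic50_se = unname(se[1]), n_h_se = unname(se[2]),
                 residual_norm = sqrt(deviance(best)),
                 non_monotone = non_monotone, fit = best),
            class = "hill_fit")
}

#' @export
print.hill_fit <- function(x, ...) {
  cat(sprintf("Hill inhibition fit: IC50 = %.4g +/- %.2g, nH = %.3g +/- %.2g\n",
              x$ic50, x$ic50_se, x$n_h, x$n_h_se))
  invisible(x)
}

#' Fit a one-site calcium block of the sodium current
#'
#' Calcium binds the selectivity filter with nanomolar affinity and blocks
#' sodium permeation; the normalized current follows `f = 1 / (1 + [Ca]/Kd)`.
#'
#' @param ca_nM Cytosolic free calcium in nM (including 0).
#' @param response Sodium currents normalized to the calcium-free level.
#' @return A list of class `ca_block_fit` with `kd_nM` and its SE.
#' @export
fit_ca_block_of_ina <- function(ca_nM, response) {
  stopifnot(length(ca_nM) == length(response), any(ca_nM == 0))
  df <- data.frame(ca = ca_nM, response = response)
  kd0 <- max(ca_nM[which.min(abs(response - 0.5))], 1e-3)
  fit <- minpack.lm::nlsLM(response ~ 1 / (1 + ca / kd), data = df,
                           start = list(kd = kd0), lower = 1e-9)
  se <- tryCatch(sqrt(diag(vcov(fit)))[1], error = function(e) NA_real_)
  structure(list(kd_nM = unname(coef(fit)["kd"]), kd_se = unname(se),
                 fit = fit), class = "ca_block_fit")
}

#' Fit single-exponential activation or deactivation kinetics
#'
#' Fits `I(t) = baseline + A (1 - exp(-t/tau))` (activation) or
#' `I(t) = baseline + A exp(-t/tau)` (deactivation) to the post-switch window
#' of a fast solution-exchange record. Currents may optionally be normalized
#' to the maximal amplitude first; tau is unaffected.
#'
#' @param time_s,current_pA The post-switch trace.
#' @param direction "activation" or "deactivation".
#' @param window Optional c(start, end) in seconds restricting the fit; must
#'   span at least 3 sample intervals.
#' @param normalize Divide the current by its maximal absolute value first.
#' @param seed Seed for the multi-start perturbations.
#' @return A list of class `kinetics_fit`: `tau_ms`, `amplitude`, `baseline`,
#'   `window`.
#' @export
fit_exponential_kinetics <- function(time_s, current_pA,
                                     direction = c("activation", "deactivation"),
                                     window = NULL, normalize = FALSE, seed = 1) {
  direction <- match.arg(direction)
  stopifnot(length(time_s) == length(current_pA), length(time_s) >= 4)
  if (!is.null(window)) {
    dt <- median(diff(time_s))
    if (diff(window) < 3 * dt) stop("fit window shorter than 3 sample intervals")
    keep <- time_s >= window[1] & time_s <= window[2]
    time_s <- time_s[keep]
    current_pA <- current_pA[keep]
  }
  if (normalize) current_pA <- current_pA / max(abs(current_pA))
  t0 <- time_s - time_s[1]
  rng <- diff(range(current_pA))
  if (rng < 1e-9) stop("trace has no resolvable amplitude to fit")
  a0 <- if (direction == "activation") current_pA[length(current_pA)] - current_pA[1]
        else current_pA[1] - current_pA[length(current_pA)]
  if (abs(a0) < 1e-9) stop("trace has no resolvable amplitude to fit")
  b0 <- if (direction == "activation") current_pA[1] else current_pA[length(current_pA)]
  tau0 <- max(diff(range(t0)) / 5, 1e-9)
  if (!is.null(seed)) set.seed(seed)
  taus <- tau0 * exp(c(0, rnorm(4, 0, 1)))
  form <- if (direction == "activation") {
    current_pA ~ baseline + amp * (1 - exp(-t0 / tau))
  } else {
    current_pA ~ baseline + amp * exp(-t0 / tau)
  }
  df <- data.frame(t0 = t0, current_pA = current_pA)
  best <- NULL
  for (tau_s in taus) {
    fit <- tryCatch(
      minpack.lm::nlsLM(form, data = df,
                        start = list(baseline = b0, amp = a0, tau = tau_s),
                        lower = c(-Inf, -Inf, 1e-12),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || deviance(fit) < deviance(best)))
      best <- fit
  }
  if (is.null(best)) stop("exponential fit failed from all starting points")
  est <- coef(best)
  structure(list(tau_ms = unname(est["tau"]) * 1000,
                 amplitude = unname(est["amp"]),
                 baseline = unname(est["baseline"]),
                 window = range(time_s), direction = direction, fit = best),
            class = "kinetics_fit")
}

#' @export
print.kinetics_fit <- function(x, ...) {
  cat(sprintf("%s kinetics: tau = %.4g ms, amplitude = %.4g, baseline = %.4g\n",
              x$direction, x$tau_ms, x$amplitude, x$baseline))
  invisible(x)
}

#' Rectification index of a ramp sweep
#'
#' Ratio of the outward current magnitude at +80 mV to the inward magnitude
#' at -160 mV. The uniporter pore rectifies inwardly: with millimolar matrix
#' calcium present no outward current develops, so the index stays below 0.01.
#'
#' @param sweep A [ramp_sweep()].
#' @param v_out,v_in Voltages for the outward and inward readouts, mV.
#' @return A list with `index`, `outward_pA` and `inward_pA`.
#' @export
rectification_index <- function(sweep, v_out = 80, v_in = -160) {
  i_out <- current_at_voltage(sweep, v_out)$current_pA
  i_in <- current_at_voltage(sweep, v_in)$current_pA
  if (abs(i_in) < 1e-12) stop("no inward current to normalize by")
  list(index = abs(i_out) / abs(i_in), outward_pA = i_out, inward_pA = i_in)
}
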