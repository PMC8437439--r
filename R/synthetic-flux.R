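#' Flux assay model for isolated-mitochondria calcium uptake
#'
#' Generative model of the plate-reader uptake assay: a bolus of calcium is
#' injected into a buffered mitochondrial suspension and the
#' extramitochondrial total calcium declines as the uniporter carries it into
#' the matrix, at the rate set by the chord-conductance relation
#' `I = G (psi_m - E_Ca)`. Matrix free calcium and the membrane potential are
#' treated as clamped during the 35-s record (matrix buffering and
#' substrate-driven respiration), so the only state variable is cumulative
#' uptake.
#'
#' The default conductance scale is chosen so that a mid-micromolar bolus
#' declines at a few hundredths of a micromolar per second, the rate scale of
#' substrate-energized mitochondrial uptake assays.
#'
#' @param true_G Membrane calcium conductance, nS per mg protein.
#' @param psi_m Membrane potential, mV (matrix negative when energized).
#' @param ca_matrix_nM Matrix free calcium, nM.
#' @param protein_mg_ml Mitochondrial protein, mg/ml.
#' @param buffers Chelators present, as in [solve_free_ca()] (uM). The
#'   reporting indicator must be included here when it buffers calcium.
#' @param indicator [indicator_calibration()] of the extramitochondrial dye
#'   (kd in uM).
#' @param matrix_fura [indicator_calibration()] of matrix-loaded fura-2 (kd
#'   in nM).
#' @param tmrm List `a`, `b` mapping potential to the TMRM ratio
#'   `ratio = a + b * psi_mV` (monotone in psi).
#' @param noise_frac Multiplicative Gaussian noise per fluorescence channel.
#' @param temperature_K Temperature.
#' @return An object of class `flux_model`.
#' @export
flux_model <- function(true_G = 2e4, psi_m = -160, ca_matrix_nM = 200,
                       protein_mg_ml = 0.5,
                       buffers = protocol_buffers(1),
                       indicator = fluo4_calibration(),
                       matrix_fura = indicator_calibration(kd = 224, r_min = 0.3,
                                                           r_max = 3, beta = 4),
                       tmrm = list(a = 0.8, b = -0.008),
                       noise_frac = 0.002, temperature_K = 298.15) {
  stopifnot(true_G >= 0, protein_mg_ml > 0, ca_matrix_nM > 0, noise_frac >= 0)
  if (psi_m >= 0) warning("psi_m >= 0: mitochondria are not energized")
  structure(list(true_G = true_G, psi_m = psi_m, ca_matrix_nM = ca_matrix_nM,
                 protein_mg_ml = protein_mg_ml, buffers = buffers,
                 indicator = indicator, matrix_fura = matrix_fura,
                 tmrm = tmrm, noise_frac = noise_frac,
                 temperature_K = temperature_K),
            class = "flux_model")
}

#' Buffer sets of the two uptake protocols
#'
#' Protocol 1 (boluses up to and including 3 uM): 3 uM Fluo-4 is the single
#' significant buffer. Protocol 2 (4-25 uM): 40 uM EGTA with 1 uM Fluo4-FF
#' as a low-affinity reporter.
#'
#' @param protocol 1 or 2, or "auto" with `ca_added` to pick by the 3 uM
#'   boundary (inclusive to protocol 1).
#' @param ca_added Added calcium in uM, used when `protocol = "auto"`.
#' @return Buffer list as consumed by [solve_free_ca()] (uM units).
#' @export
protocol_buffers <- function(protocol = 1, ca_added = NULL) {
  if (identical(protocol, "auto")) {
    stopifnot(!is.null(ca_added))
    protocol <- if (ca_added <= 3) 1 else 2
  }
  if (protocol == 1) {
    list(list(name = "Fluo4", total = 3, kd = 0.35))
  } else {
    list(list(name = "EGTA", total = 40, kd = 0.4),
         list(name = "Fluo4FF", total = 1, kd = 9.7))
  }
}

#' Fluorescence calibration of the extramitochondrial indicator
#'
#' @param protocol 1 (Fluo-4, Kd 0.35 uM) or 2 (Fluo4-FF, Kd 9.7 uM).
#' @return An [indicator_calibration()] with kd in uM.
#' @export
fluo4_calibration <- function(protocol = 1) {
  if (protocol == 1) indicator_calibration(kd = 0.35, f_min = 10, f_max = 110)
  else indicator_calibration(kd = 9.7, f_min = 10, f_max = 110)
}

#' TMRM ratio-to-potential calibration table of a flux model
#'
#' @param model A [flux_model()].
#' @param psi_range Potentials covered, mV.
#' @return data.frame with `ratio` and `psi_mV`, monotone in ratio.
#' @export
tmrm_calibration_table <- function(model, psi_range = c(-200, 0)) {
  psi <- seq(psi_range[1], psi_range[2], by = 1)
  data.frame(ratio = model$tmrm$a + model$tmrm$b * psi, psi_mV = psi)
}

#' Simulate an isolated-mitochondria calcium uptake assay
#'
#' Integrates cumulative uptake under the chord-conductance law, with the
#' extramitochondrial free calcium obtained from the buffer equilibrium at
#' every step, and renders the fluorescence channels (extramitochondrial
#' dye, matrix fura-2 pair, TMRM pair) through the stated indicator models
#' plus multiplicative noise. Exact ground truth (free, bound and cumulative
#' uptake at every sample) is attached as attribute `truth`; it satisfies
#' calcium conservation to numerical precision.
#'
#' If the membrane potential equals the calcium Nernst potential there is no
#' driving force; a zero-flux record is returned with a warning.
#'
#' @param model A [flux_model()].
#' @param ca_added Injected calcium bolus, uM.
#' @param duration Record length, s.
#' @param sample_interval Sampling interval, s.
#' @param seed Integer seed.
#' @return A list of class `flux_assay_record` with `time_s`, `F_ca_ex`,
#'   `F_fura340`, `F_fura380`, `F_tmrm_num`, `F_tmrm_den`, and metadata
#'   fields; ground truth in `attr(, "truth")`.
#' @export
simulate_flux_assay <- function(model, ca_added, duration = 35,
                                sample_interval = 0.2, seed = NULL) {
  stopifnot(inherits(model, "flux_model"), ca_added >= 0)
  if (!is.null(seed)) set.seed(seed)
  times <- seq(0, duration, by = sample_interval)
  ca_m_uM <- model$ca_matrix_nM / 1000
  protein_mg_L <- model$protein_mg_ml * 1000
  rt_zf <- 1000 * .GAS_R * model$temperature_K / (.CA_VALENCE * .FARADAY)
  uptake_rate <- function(u) {
    # u: cumulative uptake, uM of assay volume
    free <- solve_free_ca(max(ca_added - u, 0), model$buffers)$free
    if (free <= 0) return(0)
    e_ca <- rt_zf * log(free / ca_m_uM)
    drive_V <- (model$psi_m - e_ca) / 1000
    J <- -model$true_G * 1e-9 * drive_V / (.CA_VALENCE * .FARADAY)  # mol/s/mg
    max(J, 0) * protein_mg_L * 1e6                                  # uM/s
  }
  free0 <- solve_free_ca(ca_added, model$buffers)$free
  zero_drive <- FALSE
  if (model$true_G > 0 && free0 > 0) {
    e0 <- rt_zf * log(free0 / ca_m_uM)
    if (abs(model$psi_m - e0) < 1e-9) {
      zero_drive <- TRUE
      warning("psi_m equals E_Ca: zero driving force, emitting a flat record")
    }
  }
  u <- if (model$true_G == 0 || zero_drive || ca_added == 0) {
    rep(0, length(times))
  } else {
    sol <- deSolve::ode(y = c(u = 0), times = times,
                        func = function(t, y, p) list(uptake_rate(y[1])),
                        parms = NULL, rtol = 1e-10, atol = 1e-12)
    pmin(as.numeric(sol[, "u"]), ca_added)
  }
  eq <- lapply(ca_added - u, solve_free_ca, buffers = model$buffers)
  free <- vapply(eq, function(e) e$free, 0)
  bound <- do.call(rbind, lapply(eq, function(e) rbind(e$bound)))
  f_ex <- single_wavelength_f(free, model$indicator)
  r_m <- fura_ratio(model$ca_matrix_nM, model$matrix_fura)
  f380 <- rep(100, length(times))
  f340 <- r_m * f380
  tm_den <- rep(100, length(times))
  tm_num <- (model$tmrm$a + model$tmrm$b * model$psi_m) * tm_den
  noisy <- function(x) x * (1 + rnorm(length(x), 0, model$noise_frac))
  rec <- structure(list(time_s = times, F_ca_ex = noisy(f_ex),
                        F_fura340 = noisy(f340), F_fura380 = noisy(f380),
                        F_tmrm_num = noisy(tm_num), F_tmrm_den = noisy(tm_den),
                        ca_added_uM = ca_added,
                        protein_mg_ml = model$protein_mg_ml),
                   class = "flux_assay_record")
  attr(rec, "truth") <- list(uptake_uM = u, free_uM = free, bound_uM = bound,
                             total_uM = ca_added - u, true_G = model$true_G,
                             psi_m = model$psi_m,
                             ca_matrix_nM = model$ca_matrix_nM)
  rec
}
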