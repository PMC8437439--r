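#' Ratiometric indicator calibration constants
#'
#' Container for Grynkiewicz-style calibration of a ratiometric dye (fura-2,
#' Kd = 224 nM for the cytosol; matrix-loaded fura-2 uses its own constants)
#' or a single-wavelength dye (Fluo-4, Fluo4-FF).
#'
#' @param kd Dissociation constant (same concentration unit as the output).
#' @param r_min,r_max Ratio limits at zero and saturating calcium
#'   (ratiometric dyes).
#' @param beta F380max/F380min (ratiometric dyes).
#' @param f_min,f_max Fluorescence limits (single-wavelength dyes).
#' @return An object of class `indicator_calibration`.
#' @export
indicator_calibration <- function(kd, r_min = NA, r_max = NA, beta = NA,
                                  f_min = NA, f_max = NA) {
  stopifnot(kd > 0)
  if (!is.na(r_min) && (!is.na(r_max)) && r_max <= r_min)
    stop("r_max must exceed r_min")
  if (!is.na(beta) && beta <= 0) stop("beta must be positive")
  if (!is.na(f_min) && !is.na(f_max) && f_max <= f_min)
    stop("f_max must exceed f_min")
  structure(list(kd = kd, r_min = r_min, r_max = r_max, beta = beta,
                 f_min = f_min, f_max = f_max),
            class = "indicator_calibration")
}

#' Free calcium from a fura-2 ratio
#'
#' The ratiometric calibration
#' `[Ca] = Kd * (R - Rmin)/(Rmax - R) * beta` with `beta = F380max/F380min`.
#' Ratios below `r_min` are clamped to zero free calcium with a warning
#' (sub-baseline noise); ratios at or above `r_max` are a saturation error.
#'
#' @param ratio F340/F380 ratio(s).
#' @param cal An [indicator_calibration()] with `r_min`, `r_max`, `beta`.
#' @return Free calcium in the unit of `cal$kd`.
#' @export
calibrate_fura <- function(ratio, cal) {
  stopifnot(inherits(cal, "indicator_calibration"))
  if (any(ratio >= cal$r_max)) stop("fura ratio at or above r_max: indicator saturated")
  if (any(ratio < cal$r_min)) {
    warning("fura ratio below r_min; clamping to zero free calcium")
    ratio <- pmax(ratio, cal$r_min)
  }
  cal$kd * (ratio - cal$r_min) / (cal$r_max - ratio) * cal$beta
}

#' Fura-2 ratio expected at a given free calcium (calibration inverse)
#'
#' @param ca Free calcium in the unit of `cal$kd`.
#' @param cal An [indicator_calibration()].
#' @return The F340/F380 ratio.
#' @export
fura_ratio <- function(ca, cal) {
  kb <- cal$kd * cal$beta
  (cal$r_min * kb + ca * cal$r_max) / (kb + ca)
}

#' Free calcium from a single-wavelength indicator
#'
#' One-site form `[Ca] = Kd (F - Fmin)/(Fmax - F)` for Fluo-4 and Fluo4-FF
#' channels.
#'
#' @param f Fluorescence value(s).
#' @param cal An [indicator_calibration()] with `f_min`, `f_max`.
#' @return Free calcium in the unit of `cal$kd`.
#' @export
calibrate_single_wavelength <- function(f, cal) {
  stopifnot(inherits(cal, "indicator_calibration"))
  if (any(f >= cal$f_max)) stop("fluorescence at or above f_max: indicator saturated")
  if (any(f < cal$f_min)) {
    warning("fluorescence below f_min; clamping to zero free calcium")
    f <- pmax(f, cal$f_min)
  }
  cal$kd * (f - cal$f_min) / (cal$f_max - f)
}

#' Single-wavelength fluorescence at a given free calcium (inverse)
#'
#' @param ca Free calcium in the unit of `cal$kd`.
#' @param cal An [indicator_calibration()].
#' @return Fluorescence value(s).
#' @export
single_wavelength_f <- function(ca, cal) {
  cal$f_min + (cal$f_max - cal$f_min) * ca / (ca + cal$kd)
}

#' Solve the free calcium of a buffered solution
#'
#' Mass-action equilibrium for total calcium shared among one-to-one
#' chelators (EGTA, indicator dyes): solves
#' `free + sum_i total_i * free / (free + kd_i) = total` by bracketed root
#' finding. Apparent Kds are inputs; no pH or ionic-strength corrections are
#' applied.
#'
#' @param total_ca Total calcium, uM.
#' @param buffers List of `list(name, total, kd)` entries in uM, or NULL.
#' @param tol Relative conservation tolerance.
#' @return A list with `free` (uM) and `bound` (named vector per buffer).
#' @export
solve_free_ca <- function(total_ca, buffers = NULL, tol = 1e-12) {
  if (total_ca < 0) stop("total calcium must be non-negative")
  if (is.null(buffers) || length(buffers) == 0)
    return(list(free = total_ca, bound = setNames(numeric(0), character(0))))
  tot <- vapply(buffers, function(b) b$total, 0)
  kds <- vapply(buffers, function(b) b$kd, 0)
  if (any(tot < 0) || any(kds <= 0)) stop("buffer totals must be >= 0 and kds > 0")
  if (total_ca == 0) {
    bound <- setNames(rep(0, length(buffers)),
                      vapply(buffers, function(b) b$name, ""))
    return(list(free = 0, bound = bound))
  }
  g <- function(f) f + sum(tot * f / (f + kds)) - total_ca
  free <- stats::uniroot(g, c(0, total_ca), tol = tol * max(total_ca, 1))$root
  bound <- setNames(tot * free / (free + kds),
                    vapply(buffers, function(b) b$name, ""))
  list(free = free, bound = bound)
}

#' Total calcium implied by a free concentration (equilibrium inverse)
#'
#' @param free Free calcium, uM.
#' @param buffers As in [solve_free_ca()].
#' @return Total calcium, uM.
#' @export
total_from_free <- function(free, buffers = NULL) {
  if (is.null(buffers) || length(buffers) == 0) return(free)
  tot <- vapply(buffers, function(b) b$total, 0)
  kds <- vapply(buffers, function(b) b$kd, 0)
  vapply(free, function(f) f + sum(tot * f / (f + kds)), 0)
}

#' Estimate the calcium flux from the extramitochondrial decline
#'
#' Ordinary least-squares slope of the total extramitochondrial calcium over
#' the stated window (the first 20 s of the record by default), signed so
#' that uptake into mitochondria gives a positive flux, and normalized by the
#' protein concentration.
#'
#' @param time_s Sample times, s.
#' @param total_ca_uM Total extramitochondrial calcium, uM.
#' @param protein_mg_ml Mitochondrial protein concentration, mg/ml.
#' @param window c(start, end) in seconds; default first 20 s.
#' @return A list with `J` (mol s^-1 mg^-1), `slope_uM_s`, and `n`.
#' @export
estimate_flux <- function(time_s, total_ca_uM, protein_mg_ml,
                          window = c(0, 20)) {
  keep <- time_s >= window[1] & time_s <= window[2]
  if (sum(keep) < 4) stop("flux window contains fewer than 4 points")
  fit <- lm(total_ca_uM[keep] ~ time_s[keep])
  slope <- unname(coef(fit)[2])           # uM/s of assay volume
  # uM/s -> mol/L/s, protein mg/ml -> mg/L; uptake (decline) is positive J
  j <- -slope * 1e-6 / (protein_mg_ml * 1000)
  list(J = j, slope_uM_s = slope, n = sum(keep))
}

#' Nernst reversal potential for calcium
#'
#' `E_Ca = (R T / z F) ln([Ca]_i / [Ca]_m)` with z = 2, in mV. Both
#' concentrations must be in the same unit and positive. With the
#' matrix-minus-cytosol voltage convention used throughout, `psi_m - E_Ca` is
#' the driving force for calcium influx.
#'
#' @param ca_i_free Cytosolic (extramitochondrial) free calcium.
#' @param ca_m_free Matrix free calcium, same unit.
#' @param temperature_K Temperature in kelvin (room temperature default).
#' @return Potential in mV.
#' @export
nernst_eca <- function(ca_i_free, ca_m_free, temperature_K = 298.15) {
  if (any(ca_i_free <= 0) || any(ca_m_free <= 0))
    stop("Nernst potential needs positive free concentrations on both sides")
  1000 * .GAS_R * temperature_K / (.CA_VALENCE * .FARADAY) *
    log(ca_i_free / ca_m_free)
}

#' Chord conductance from a calcium flux
#'
#' Converts a molar flux to a current with the Faraday constant
#' (`I = -z F J`; influx J > 0 gives an inward, negative current) and divides
#' by the driving force: `G = I / (psi_m - E_Ca)`.
#'
#' @param J Calcium flux, mol s^-1 mg^-1 (positive into the matrix).
#' @param psi_m Membrane potential, mV (matrix negative when energized).
#' @param e_ca Nernst potential from [nernst_eca()], mV.
#' @return A list with `I` (A/mg), `G` (S/mg) and `G_nS` (nS/mg).
#' @export
chord_conductance <- function(J, psi_m, e_ca) {
  drive_V <- (psi_m - e_ca) / 1000
  if (abs(drive_V) < 1e-3)
    stop("driving force below 1 mV: chord conductance undefined")
  I <- -.CA_VALENCE * .FARADAY * J
  G <- I / drive_V
  list(I = I, G = G, G_nS = G * 1e9)
}

#' Recover the membrane conductance from a simulated or measured flux assay
#'
#' Full inference pipeline for one plate-reader record: calibrate the
#' extramitochondrial indicator, reconstruct total calcium through the buffer
#' equilibria, fit the flux over the first 20 s, calibrate matrix calcium
#' from the matrix fura-2 ratio, read the membrane potential from the TMRM
#' ratio through a monotone calibration table (or take it directly), and
#' combine everything into a chord conductance.
#'
#' @param record A `flux_assay_record` (see [simulate_flux_assay()]) or any
#'   list with `time_s`, `F_ca_ex`, `F_fura340`, `F_fura380`, `F_tmrm_num`,
#'   `F_tmrm_den`.
#' @param indicator_cal [indicator_calibration()] for the extramitochondrial
#'   dye (uM).
#' @param buffers Buffer list as in [solve_free_ca()] (excluding the
#'   indicator itself if it is listed separately; include it here - the
#'   indicator is a buffer too).
#' @param matrix_cal [indicator_calibration()] for matrix fura-2 (nM).
#' @param protein_mg_ml Protein concentration, mg/ml.
#' @param psi_m Membrane potential in mV, or NULL to use `tmrm_table`.
#' @param tmrm_table data.frame with columns `ratio` and `psi_mV` mapping the
#'   TMRM ratio to potential (monotone).
#' @param window Flux window in seconds.
#' @param temperature_K Temperature.
#' @return A list of class `conductance_point` with `ca_i_free_uM`,
#'   `ca_m_free_nM`, `psi_m`, `J`, `I`, `e_ca`, `G_nS`.
#' @export
recover_conductance <- function(record, indicator_cal, buffers,
                                matrix_cal, protein_mg_ml,
                                psi_m = NULL, tmrm_table = NULL,
                                window = c(0, 20), temperature_K = 298.15) {
  free <- calibrate_single_wavelength(record$F_ca_ex, indicator_cal)
  total <- total_from_free(free, buffers)
  fl <- estimate_flux(record$time_s, total, protein_mg_ml, window)
  keep <- record$time_s >= window[1] & record$time_s <= window[2]
  ca_m <- median(calibrate_fura(record$F_fura340[keep] / record$F_fura380[keep],
                                matrix_cal))
  if (is.null(psi_m)) {
    if (is.null(tmrm_table)) stop("supply psi_m or a TMRM calibration table")
    ratio <- record$F_tmrm_num[keep] / record$F_tmrm_den[keep]
    psi_m <- median(approx(tmrm_table$ratio, tmrm_table$psi_mV,
                           xout = ratio, rule = 2)$y)
  }
  # per-sample Nernst potential averaged over the window, so the chord
  # relation holds on window averages even as free calcium declines
  e_ca <- mean(nernst_eca(free[keep] * 1e-6, ca_m * 1e-9, temperature_K))
  cc <- chord_conductance(fl$J, psi_m, e_ca)
  structure(list(ca_i_free_uM = mean(free[keep]), ca_m_free_nM = ca_m,
                 psi_m = psi_m, J = fl$J, I = cc$I, e_ca = e_ca,
                 G = cc$G, G_nS = cc$G_nS, slope_uM_s = fl$slope_uM_s),
            class = "conductance_point")
}

#' @export
print.conductance_point <- function(x, ...) {
  cat(sprintf(paste0("conductance point: [Ca]i = %.3g uM, [Ca]m = %.3g nM, ",
                     "psi = %.1f mV, E_Ca = %.1f mV\n  J = %.3g mol/s/mg, ",
                     "G = %.4g nS/mg\n"),
              x$ca_i_free_uM, x$ca_m_free_nM, x$psi_m, x$e_ca, x$J, x$G_nS))
  invisible(x)
}

#' Conductance versus cytosolic calcium curve with genotype crossover
#'
#' Bins conductance points by cytosolic free calcium, reports mean and SEM
#' per genotype and bin, and locates the crossover: MICU1-KO conducts more
#' than WT at sub-threshold calcium but less once MICU potentiation engages
#' (around 8 uM).
#'
#' @param points data.frame with columns `ca_i_uM`, `G_nS`, `genotype` (two
#'   levels).
#' @param breaks Bin edges for `ca_i_uM` (log-spaced default).
#' @return A list with `curve` (per-genotype, per-bin summary data.frame) and
#'   `crossover_uM` (geometric mid-point of the bin where the genotype
#'   difference changes sign, or NA).
#' @export
g_vs_ca_curve <- function(points, breaks = NULL) {
  stopifnot(all(c("ca_i_uM", "G_nS", "genotype") %in% names(points)))
  if (is.null(breaks))
    breaks <- exp(seq(log(max(min(points$ca_i_uM) * 0.99, 1e-6)),
                      log(max(points$ca_i_uM) * 1.01), length.out = 9))
  points$bin <- cut(points$ca_i_uM, breaks, include.lowest = TRUE)
  agg <- do.call(rbind, lapply(split(points, list(points$genotype, points$bin),
                                     drop = TRUE), function(d)
    data.frame(genotype = d$genotype[1], bin = d$bin[1],
               ca_mid = exp(mean(log(d$ca_i_uM))), n = nrow(d),
               G_mean = mean(d$G_nS),
               G_sem = sd(d$G_nS) / sqrt(max(nrow(d), 1)))))
  rownames(agg) <- NULL
  gts <- unique(as.character(points$genotype))
  crossover <- NA_real_
  if (length(gts) == 2) {
    a <- agg[agg$genotype == gts[1], c("bin", "ca_mid", "G_mean")]
    b <- agg[agg$genotype == gts[2], c("bin", "G_mean")]
    w <- merge(a, b, by = "bin", suffixes = c("_a", "_b"))
    w <- w[order(w$ca_mid), ]
    d <- w$G_mean_a - w$G_mean_b
    flip <- which(diff(sign(d)) != 0)
    if (length(flip) > 0) {
      # zero of the genotype difference, interpolated on log concentration
      i <- flip[1]
      lx <- log(w$ca_mid[i:(i + 1)])
      crossover <- exp(lx[1] - d[i] * diff(lx) / (d[i + 1] - d[i]))
    }
  }
  list(curve = agg, crossover_uM = crossover)
}

#' Depolarization expressed as percent of the FCCP response
#'
#' The potentiometric-dye ratio change caused by an event (EDTA-induced
#' sodium influx, ruthenium red) is normalized to the full depolarization by
#' the uncoupler FCCP, each evaluated over a 5-minute post-injection window.
#'
#' @param time_s,ratio TMRE ratio trace.
#' @param event_time,fccp_time Injection times, s.
#' @param window_s Post-injection window length, s.
#' @param baseline_s Pre-injection span averaged as the reference, s.
#' @return A list with `percent_of_fccp`, `delta_event`, `delta_fccp`.
#' @export
depolarization_index <- function(time_s, ratio, event_time, fccp_time,
                                 window_s = 300, baseline_s = 30) {
  win_mean <- function(t0, t1) {
    keep <- time_s >= t0 & time_s <= t1
    if (!any(keep)) stop("window contains no samples")
    mean(ratio[keep])
  }
  d_event <- win_mean(event_time + 0.8 * window_s, event_time + window_s) -
    win_mean(event_time - baseline_s, event_time)
  d_fccp <- win_mean(fccp_time + 0.8 * window_s, fccp_time + window_s) -
    win_mean(fccp_time - baseline_s, fccp_time)
  if (abs(d_fccp) < 1e-12) stop("FCCP produced no ratio change to normalize by")
  list(percent_of_fccp = 100 * d_event / d_fccp,
       delta_event = d_event, delta_fccp = d_fccp)
}
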