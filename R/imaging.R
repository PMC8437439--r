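#' Normalize a fluorescence series to its pre-stimulus baseline
#'
#' Divides by the mean of the baseline window, giving F/F0. Invariant to a
#' common gain on the raw intensities.
#'
#' @param values Fluorescence intensities.
#' @param baseline_frames Indices of the pre-stimulus frames.
#' @return F/F0 series.
#' @export
normalize_f0 <- function(values, baseline_frames) {
  f0 <- mean(values[baseline_frames])
  if (!is.finite(f0) || f0 <= 0) stop("baseline mean must be positive")
  values / f0
}

#' Zero-phase second-order Butterworth smoothing
#'
#' Forward-backward application of a second-order low-pass Butterworth
#' filter: zero phase lag (onsets are not shifted in time) and unit DC gain.
#'
#' @param series Uniformly sampled values.
#' @param cutoff_hz Cutoff frequency; must be below Nyquist.
#' @param fs Sampling rate, Hz.
#' @return Smoothed series.
#' @export
zero_phase_butterworth <- function(series, cutoff_hz, fs) {
  if (cutoff_hz >= fs / 2) stop("cutoff must be below the Nyquist frequency")
  if (cutoff_hz <= 0) stop("cutoff must be positive")
  bf <- signal::butter(2, cutoff_hz / (fs / 2), type = "low")
  # reflect-pad by a few filter time constants so the zero initial
  # conditions of the underlying filter do not leak transients into the ends
  n <- length(series)
  pad <- min(n - 1, ceiling(6 * fs / cutoff_hz))
  x <- c(rev(series[seq_len(pad) + 1]), series,
         rev(series[seq(n - pad, n - 1)]))
  y <- as.numeric(signal::filtfilt(bf, x))
  y[pad + seq_len(n)]
}

#' Residual-analysis selection of the smoothing cutoff
#'
#' Chooses the cutoff where the RMS residual between the raw and filtered
#' series meets the noise floor extrapolated from the high-cutoff (noise
#' dominated) limb of the residual-versus-cutoff curve. When the residual
#' curve is too flat to characterize (essentially noise-free data) the
#' highest candidate is returned, i.e. minimal smoothing.
#'
#' @param series Uniformly sampled values.
#' @param fs Sampling rate, Hz.
#' @param candidates Candidate cutoffs; default 30 log-spaced values up to
#'   90% of Nyquist.
#' @return Selected cutoff in Hz.
#' @export
select_filter_cutoff <- function(series, fs, candidates = NULL) {
  nyq <- fs / 2
  if (is.null(candidates))
    candidates <- exp(seq(log(0.02 * nyq), log(0.9 * nyq), length.out = 30))
  rms <- vapply(candidates, function(fc)
    sqrt(mean((series - zero_phase_butterworth(series, fc, fs))^2)), 0)
  hi <- candidates >= 0.4 * nyq
  if (sum(hi) < 3 || max(rms) < 1e-12 * max(abs(series), 1))
    return(max(candidates))
  fit <- lm(rms[hi] ~ candidates[hi])
  floor_rms <- unname(coef(fit)[1])
  if (!is.finite(floor_rms) || floor_rms <= 0) return(max(candidates))
  below <- which(rms <= floor_rms)
  if (length(below) == 0) return(max(candidates))
  candidates[min(below)]
}

#' Detect the mitochondrial uptake upstroke frame
#'
#' On the smoothed mitochondrial series, computes the central-difference time
#' derivative, restricts attention to the interval between the end of the
#' baseline and the global signal peak, and returns the earliest frame whose
#' derivative exceeds 80% of the maximal derivative in that interval (ties
#' broken toward the earliest index).
#'
#' Quality-control flags replace the manual inspection step: a peak occurring
#' before the stimulus, a criterion met at the interval boundary, and a flat
#' trace (which is an error).
#'
#' @param smoothed Smoothed mitochondrial F/F0 series.
#' @param baseline_end Last frame of the pre-stimulus baseline.
#' @param stimulus_frame Frame of stimulus addition (for QC only).
#' @param deriv_fraction Fraction of the maximal derivative (0.8).
#' @return A list with `upstroke_frame`, `peak_frame`, `max_derivative`,
#'   `qc_flags` (character vector).
#' @export
detect_upstroke <- function(smoothed, baseline_end,
                            stimulus_frame = baseline_end,
                            deriv_fraction = 0.8) {
  n <- length(smoothed)
  if (n < 5) stop("series too short for upstroke detection")
  base <- smoothed[seq_len(max(baseline_end, 2))]
  rise <- max(smoothed) - mean(base)
  if (rise <= max(5 * sd(base), 1e-9 * max(abs(smoothed))))
    stop("no upstroke: trace is flat relative to its baseline")
  qc <- character(0)
  peak <- which.max(smoothed)
  if (peak <= stimulus_frame) qc <- c(qc, "peak_before_stimulus")
  deriv <- c(NA, (smoothed[-(1:2)] - smoothed[1:(n - 2)]) / 2, NA)
  lo <- max(baseline_end + 1, 2)
  hi <- min(peak, n - 1)
  if (hi <= lo) stop("no interior interval between baseline and peak")
  idx <- lo:hi
  dmax <- max(deriv[idx], na.rm = TRUE)
  if (dmax <= 0) stop("no upstroke: derivative never positive before the peak")
  cand <- idx[which(deriv[idx] >= deriv_fraction * dmax)]
  frame <- cand[1]
  if (frame == lo) qc <- c(qc, "criterion_at_boundary")
  list(upstroke_frame = frame, peak_frame = peak, max_derivative = dmax,
       qc_flags = qc)
}

#' Cytosolic calcium threshold at the detected upstroke
#'
#' Time-matches the fura-2 ratio to the upstroke frame of the mitochondrial
#' signal and calibrates it to a free concentration.
#'
#' @param trace An `imaging_trace` (see [simulate_imaging()]).
#' @param upstroke_frame Frame index from [detect_upstroke()].
#' @param cal [indicator_calibration()] for fura-2 (kd in nM).
#' @return Threshold cytosolic calcium, nM.
#' @export
threshold_ca <- function(trace, upstroke_frame, cal) {
  r <- trace$f340[upstroke_frame] / trace$f380[upstroke_frame]
  calibrate_fura(r, cal)
}

#' Analyze one imaging trace: smooth, detect, calibrate
#'
#' Runs the full per-cell pipeline: F/F0 normalization of the mitochondrial
#' channel, zero-phase Butterworth smoothing (auto cutoff by residual
#' analysis, fixed fallback 0.03 Hz for 3-s frame data), derivative-criterion
#' upstroke detection, and threshold calibration from the time-matched fura-2
#' ratio. A saturated fura ratio at the upstroke adds a QC flag.
#'
#' @param trace An `imaging_trace`.
#' @param cal Fura-2 [indicator_calibration()] (kd nM).
#' @param stimulus_time Thapsigargin addition time, s; defaults to the
#'   trace's recorded value.
#' @param cutoff "auto" or a cutoff in Hz.
#' @return A list of class `threshold_result`: `upstroke_frame`,
#'   `upstroke_time_s`, `threshold_ca_nM`, `filter_cutoff_used`, `qc_flags`.
#' @export
analyze_imaging_trace <- function(trace, cal, stimulus_time = NULL,
                                  cutoff = "auto") {
  stopifnot(inherits(trace, "imaging_trace") || is.list(trace))
  if (is.null(stimulus_time)) stimulus_time <- trace$stim_time_s
  fs <- 1 / trace$frame_interval_s
  baseline_end <- max(which(trace$time_s <= stimulus_time))
  ff0 <- normalize_f0(trace$f_cepia, seq_len(baseline_end))
  fc <- if (identical(cutoff, "auto")) {
    tryCatch(select_filter_cutoff(ff0, fs), error = function(e) 0.03)
  } else cutoff
  sm <- zero_phase_butterworth(ff0, fc, fs)
  det <- detect_upstroke(sm, baseline_end,
                         stimulus_frame = baseline_end)
  qc <- det$qc_flags
  thr <- tryCatch(threshold_ca(trace, det$upstroke_frame, cal),
                  error = function(e) {
                    qc <<- c(qc, "fura_saturated")
                    NA_real_
                  })
  structure(list(upstroke_frame = det$upstroke_frame,
                 upstroke_time_s = trace$time_s[det$upstroke_frame],
                 threshold_ca_nM = thr, filter_cutoff_used = fc,
                 qc_flags = qc, cell_id = trace$cell_id,
                 dish_id = trace$dish_id),
            class = "threshold_result")
}

#' @export
print.threshold_result <- function(x, ...) {
  cat(sprintf("upstroke at frame %d (t = %.0f s), threshold [Ca]i = %.0f nM (cutoff %.3g Hz)\n",
              x$upstroke_frame, x$upstroke_time_s, x$threshold_ca_nM,
              x$filter_cutoff_used))
  if (length(x$qc_flags)) cat("  QC:", paste(x$qc_flags, collapse = ", "), "\n")
  invisible(x)
}

#' Group statistics of uptake thresholds across dishes and genotypes
#'
#' Cell-level thresholds are first aggregated to dish means (the dish is the
#' statistical unit), then compared across genotypes with a one-way ANOVA
#' and Tukey's post-hoc test.
#'
#' @param results data.frame with columns `threshold_ca_nM`, `dish_id`,
#'   `genotype`.
#' @return A list with `dish_means`, `group_summary` (mean, SEM, n of dishes
#'   per genotype), `anova_p`, and `tukey` (or NULL with < 2 groups).
#' @export
batch_thresholds <- function(results) {
  stopifnot(all(c("threshold_ca_nM", "dish_id", "genotype") %in% names(results)))
  results <- results[is.finite(results$threshold_ca_nM), ]
  dish <- aggregate(threshold_ca_nM ~ dish_id + genotype, data = results,
                    FUN = mean)
  gs <- do.call(rbind, lapply(split(dish, dish$genotype), function(d)
    data.frame(genotype = d$genotype[1], n_dishes = nrow(d),
               mean = mean(d$threshold_ca_nM),
               sem = sd(d$threshold_ca_nM) / sqrt(nrow(d)))))
  rownames(gs) <- NULL
  anova_p <- NA_real_
  tukey <- NULL
  if (length(unique(dish$genotype)) >= 2 && nrow(dish) > length(unique(dish$genotype))) {
    dish$genotype <- factor(dish$genotype)
    fit <- aov(threshold_ca_nM ~ genotype, data = dish)
    anova_p <- summary(fit)[[1]][["Pr(>F)"]][1]
    tukey <- TukeyHSD(fit)
  }
  list(dish_means = dish, group_summary = gs, anova_p = anova_p, tukey = tukey)
}
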