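#' Imaging model for thapsigargin-evoked calcium transients
#'
#' Generative model of paired cytosolic (fura-2) and mitochondrial (Cepia)
#' traces imaged at 3-s intervals. After thapsigargin addition the cytosolic
#' free calcium rises saturating-exponentially from the resting level toward
#' a plateau; the mitochondrial signal stays at baseline until the cytosolic
#' concentration crosses the programmed threshold, then rises
#' mono-exponentially. In WT-like cells the threshold sits near 400 nM; in
#' MICU1-KO-like cells uptake starts at the resting level (no delay).
#'
#' The fura channels are rendered through a two-state dye model whose ratio
#' obeys the standard ratiometric calibration exactly, so the calibration
#' inverse recovers the programmed concentrations.
#'
#' @param threshold_ca_nM Cytosolic free calcium at mitochondrial uptake
#'   onset, nM. Must lie between baseline and peak. Use the baseline value
#'   for a no-delay (MICU1-KO-like) cell.
#' @param baseline_ca_nM Resting cytosolic calcium, nM.
#' @param peak_ca_nM Plateau of the thapsigargin response, nM.
#' @param stim_time_s Thapsigargin addition time, s.
#' @param rise_tau_s Time constant of the cytosolic rise, s.
#' @param mito_gain Plateau F/F0 increase of the mitochondrial channel.
#' @param mito_tau_s Rise time constant of the mitochondrial signal, s.
#' @param frame_interval_s Imaging interval (3 s).
#' @param noise_frac Multiplicative Gaussian noise per channel.
#' @param fura [indicator_calibration()] for cytosolic fura-2 (kd in nM).
#' @param onset_time_s Optional explicit onset time; by default derived by
#'   inverting the cytosolic ramp at the threshold.
#' @return An object of class `imaging_model`.
#' @export
imaging_model <- function(threshold_ca_nM = 400, baseline_ca_nM = 100,
                          peak_ca_nM = 1000, stim_time_s = 120,
                          rise_tau_s = 100, mito_gain = 3, mito_tau_s = 20,
                          frame_interval_s = 3, noise_frac = 0.005,
                          fura = indicator_calibration(kd = 224, r_min = 0.3,
                                                       r_max = 3, beta = 4),
                          onset_time_s = NULL) {
  stopifnot(frame_interval_s > 0, peak_ca_nM > baseline_ca_nM,
            threshold_ca_nM >= baseline_ca_nM, threshold_ca_nM < peak_ca_nM,
            rise_tau_s > 0, mito_tau_s > 0, noise_frac >= 0, mito_gain >= 0)
  if (is.null(onset_time_s)) {
    onset_time_s <- if (threshold_ca_nM <= baseline_ca_nM) stim_time_s else {
      stim_time_s - rise_tau_s *
        log(1 - (threshold_ca_nM - baseline_ca_nM) / (peak_ca_nM - baseline_ca_nM))
    }
  }
  structure(list(threshold_ca_nM = threshold_ca_nM,
                 baseline_ca_nM = baseline_ca_nM, peak_ca_nM = peak_ca_nM,
                 stim_time_s = stim_time_s, rise_tau_s = rise_tau_s,
                 mito_gain = mito_gain, mito_tau_s = mito_tau_s,
                 frame_interval_s = frame_interval_s, noise_frac = noise_frac,
                 fura = fura, onset_time_s = onset_time_s),
            class = "imaging_model")
}

#' Cytosolic calcium time course of an imaging model
#'
#' @param model An [imaging_model()].
#' @param time_s Times, s.
#' @return Free calcium in nM.
#' @export
cyto_ramp <- function(model, time_s) {
  ifelse(time_s <= model$stim_time_s, model$baseline_ca_nM,
         model$baseline_ca_nM + (model$peak_ca_nM - model$baseline_ca_nM) *
           (1 - exp(-(time_s - model$stim_time_s) / model$rise_tau_s)))
}

#' Simulate a paired cytosolic/mitochondrial imaging trace
#'
#' @param model An [imaging_model()].
#' @param duration Recording length, s.
#' @param seed Integer seed.
#' @param cell_id,dish_id Labels carried into the trace.
#' @return A list of class `imaging_trace` with `time_s`, `f340`, `f380`,
#'   `f_cepia`, the frame interval and labels; ground truth (onset time,
#'   onset frame, threshold) in `attr(, "truth")`.
#' @export
simulate_imaging <- function(model, duration = 720, seed = NULL,
                             cell_id = "cell1", dish_id = "dish1") {
  stopifnot(inherits(model, "imaging_model"))
  if (model$onset_time_s < 0 || model$onset_time_s > duration)
    stop("onset time falls outside the recording")
  if (!is.null(seed)) set.seed(seed)
  tm <- seq(0, duration, by = model$frame_interval_s)
  ca <- cyto_ramp(model, tm)
  cal <- model$fura
  x <- ca / (ca + cal$kd)                       # fraction of calcium-bound dye
  f380max <- 100
  f380min <- f380max / cal$beta
  f340min <- cal$r_min * f380max
  f340max <- cal$r_max * f380min
  f340 <- f340min * (1 - x) + f340max * x
  f380 <- f380max * (1 - x) + f380min * x
  f_cepia <- 100 * (1 + model$mito_gain *
                      pmax(0, 1 - exp(-(tm - model$onset_time_s) / model$mito_tau_s)) *
                      (tm > model$onset_time_s))
  noisy <- function(v) v * (1 + rnorm(length(v), 0, model$noise_frac))
  rec <- structure(list(time_s = tm, f340 = noisy(f340), f380 = noisy(f380),
                        f_cepia = noisy(f_cepia),
                        frame_interval_s = model$frame_interval_s,
                        stim_time_s = model$stim_time_s,
                        cell_id = cell_id, dish_id = dish_id),
                   class = "imaging_trace")
  attr(rec, "truth") <- list(onset_time_s = model$onset_time_s,
                             onset_frame = which(tm > model$onset_time_s)[1],
                             threshold_ca_nM = model$threshold_ca_nM,
                             ca_nM = ca)
  rec
}
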