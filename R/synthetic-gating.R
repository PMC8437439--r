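#' Gating model for single MCU channel simulation
#'
#' Describes a discrete-state Markov model of a single uniporter channel with
#' one closed level and several conducting levels, including the prominent
#' subconductances at roughly 80% and 60% of the fully open current. The
#' transition matrix is defined per sampling step at `base_rate`; analyses
#' that resample the trace rescale it by matrix power so the ground truth
#' stays well defined across rates.
#'
#' MICU regulation is represented by `micu_potentiation`: a Hill function of
#' cytosolic free calcium that multiplies the closed-to-open transition
#' probabilities (and only those; conductance amplitudes are untouched, which
#' is what the single-channel phenotype shows). The EF-hand affinity default
#' of 600 nM reflects calcium binding to MICU EF hands.
#'
#' @param level_currents Mean current of each conductance level in pA. Level 1
#'   is the closed state and must be exactly 0. Open levels must share a sign.
#'   Defaults to a full level of -2 pA with sublevels at 80% and 60% of it
#'   (holding potential -120 mV, calcium as charge carrier).
#' @param transition_matrix Row-stochastic matrix of per-step transition
#'   probabilities at `base_rate`.
#' @param noise_sd Standard deviation of the white Gaussian recording noise
#'   (pA) added before anti-alias filtering.
#' @param voltage Holding potential, mV on the matrix side relative to the
#'   cytosolic side.
#' @param base_rate Sampling rate (Hz) at which `transition_matrix` is
#'   defined.
#' @param micu_potentiation List with `ec50_nM`, `hill` and `max_fold`
#'   describing calcium-dependent potentiation of channel opening.
#' @param permeant_ion,genotype Labels carried into simulated recordings.
#' @return An object of class `gating_model`.
#' @export
gating_model <- function(level_currents = c(0, -2.0, -1.6, -1.2),
                         transition_matrix = NULL,
                         noise_sd = 0.9,
                         voltage = -120,
                         base_rate = 50000,
                         micu_potentiation = list(ec50_nM = 600, hill = 1,
                                                  max_fold = 2.5),
                         permeant_ion = "Ca",
                         genotype = "WT") {
  K <- length(level_currents)
  if (K < 2) stop("need at least a closed and one open level")
  if (level_currents[1] != 0) stop("level 1 is the closed state; its current must be exactly 0")
  open <- level_currents[-1]
  if (any(open == 0) || length(unique(sign(open))) != 1)
    stop("open-level currents must be non-zero and share one sign")
  if (is.null(transition_matrix)) transition_matrix <- default_mcu_transitions(K)
  check_stochastic(transition_matrix, K)
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (base_rate <= 0) stop("base_rate must be positive")
  if (!is.null(micu_potentiation)) {
    if (micu_potentiation$ec50_nM <= 0) stop("MICU EC50 must be positive")
    if (micu_potentiation$max_fold < 1) stop("max_fold must be >= 1")
  }
  structure(list(level_currents = level_currents,
                 transition_matrix = transition_matrix,
                 noise_sd = noise_sd, voltage = voltage,
                 base_rate = base_rate,
                 micu_potentiation = micu_potentiation,
                 permeant_ion = permeant_ion, genotype = genotype),
            class = "gating_model")
}

check_stochastic <- function(P, K = nrow(P), tol = 1e-12) {
  if (!is.matrix(P) || nrow(P) != K || ncol(P) != K)
    stop("transition matrix must be a square K x K matrix")
  if (any(P < 0)) stop("transition probabilities must be non-negative")
  if (any(abs(rowSums(P) - 1) > tol))
    stop("transition matrix rows must sum to 1 within ", tol)
  invisible(TRUE)
}

#' Default per-step transition matrix for a K-level channel
#'
#' Slow openings and comparatively brief open dwells at the 50 kHz base rate:
#' mean closed dwells of ~20 ms and open dwells of ~5 ms, with occasional
#' direct transitions among the conducting levels.
#'
#' @param K Number of levels (closed + open).
#' @param p_open Per-step probability of leaving the closed state into each
#'   open level.
#' @param p_close Per-step probability of an open level closing.
#' @param p_switch Per-step probability of hopping to each other open level.
#' @return A K x K row-stochastic matrix.
#' @export
default_mcu_transitions <- function(K, p_open = 3e-4, p_close = 4e-3,
                                    p_switch = 2e-4) {
  P <- matrix(0, K, K)
  P[1, -1] <- p_open
  P[1, 1] <- 1 - sum(P[1, -1])
  for (i in seq_len(K)[-1]) {
    P[i, 1] <- p_close
    P[i, setdiff(seq_len(K)[-1], i)] <- p_switch
    P[i, i] <- 1 - sum(P[i, -i])
  }
  if (any(diag(P) <= 0)) stop("transition probabilities too large for a valid matrix")
  P
}

#' Stationary distribution of a row-stochastic matrix
#'
#' Computed from the leading left eigenvector.
#'
#' @param P Row-stochastic square matrix.
#' @return Probability vector over states.
#' @export
stationary_distribution <- function(P) {
  check_stochastic(P, tol = 1e-9)
  e <- eigen(t(P))
  i <- which.min(abs(e$values - 1))
  v <- Re(e$vectors[, i])
  v <- v / sum(v)
  if (any(v < -1e-10)) stop("no non-negative stationary vector found")
  pmax(v, 0) / sum(pmax(v, 0))
}

#' Stationary open probability of a gating model
#'
#' Fraction of time spent in any conducting level under the model's
#' transition matrix.
#'
#' @param model A [gating_model()].
#' @return Open probability in \[0, 1\].
#' @export
open_probability <- function(model) {
  pi <- stationary_distribution(model$transition_matrix)
  sum(pi[-1])
}

#' Apply MICU potentiation at a given cytosolic calcium level
#'
#' Multiplies the closed-to-open transition probabilities by a Hill function
#' of cytosolic free calcium (EC50 at the EF-hand affinity), renormalizing the
#' closed-state row. Open-level amplitudes are unchanged, so potentiation acts
#' purely through open probability.
#'
#' @param model A [gating_model()].
#' @param ca_nM Cytosolic free calcium in nM.
#' @return A new `gating_model` with the potentiated transition matrix.
#' @export
apply_micu_potentiation <- function(model, ca_nM) {
  stopifnot(inherits(model, "gating_model"), ca_nM >= 0)
  pot <- model$micu_potentiation
  if (is.null(pot)) return(model)
  h <- pot$hill
  fold <- 1 + (pot$max_fold - 1) * ca_nM^h / (ca_nM^h + pot$ec50_nM^h)
  scale_opening(model, fold)
}

# Multiply the closed->open probabilities by `fold` and renormalize the
# closed row. Errors if the row would leave the simplex.
scale_opening <- function(model, fold) {
  P <- model$transition_matrix
  P[1, -1] <- P[1, -1] * fold
  if (sum(P[1, -1]) >= 1) stop("opening probabilities exceed 1 after scaling")
  P[1, 1] <- 1 - sum(P[1, -1])
  model$transition_matrix <- P
  model
}

#' Rescale the closed-to-open probabilities to hit a target open probability
#'
#' Solves (by bisection on the scaling factor) for the multiplier of the
#' closed-to-open transition probabilities that gives the requested stationary
#' open probability. Used to program exact open-probability contrasts between
#' genotypes while keeping amplitudes and closing rates identical.
#'
#' @param model A [gating_model()].
#' @param po Target stationary open probability (0 < po < 1).
#' @return A new `gating_model`.
#' @export
set_open_probability <- function(model, po) {
  stopifnot(po > 0, po < 1)
  f <- function(s) open_probability(scale_opening(model, s)) - po
  s_hi <- 0.999 / sum(model$transition_matrix[1, -1])
  if (f(s_hi) < 0) stop("target open probability unreachable for this model")
  s <- stats::uniroot(f, c(1e-8, s_hi), tol = 1e-12)$root
  scale_opening(model, s)
}

#' Rescale a per-step transition matrix to a new sampling rate
#'
#' Raises the matrix to the power `factor` (an integer decimation factor), so
#' a matrix defined per 50 kHz step can be expressed per 2.5 kHz step.
#'
#' @param P Row-stochastic matrix.
#' @param factor Positive integer power.
#' @return Row-stochastic matrix at the coarser step.
#' @export
rescale_transitions <- function(P, factor) {
  stopifnot(factor >= 1, abs(factor - round(factor)) < 1e-8)
  factor <- round(factor)
  out <- diag(nrow(P))
  base <- P
  while (factor > 0) {
    if (factor %% 2 == 1) out <- out %*% base
    base <- base %*% base
    factor <- factor %/% 2
  }
  out / rowSums(out)
}

#' Simulate a single-channel current recording
#'
#' Samples a hidden Markov state path at the model's base rate, emits the
#' level currents plus white Gaussian noise, and applies a zero-phase
#' second-order Butterworth low-pass filter as the anti-alias stage (standing
#' in for the recording hardware's analogue filter). The exact hidden state
#' path is returned alongside the trace.
#'
#' @param model A [gating_model()].
#' @param duration Recording length in seconds.
#' @param sample_rate Acquisition rate in Hz (defaults to the model's base
#'   rate; the transition matrix is rescaled when they differ).
#' @param filter_cutoff Low-pass cutoff in Hz; must be below Nyquist.
#' @param seed Integer seed; identical (model, seed) gives identical output.
#' @param init_state Optional initial state index (1 = closed). Default draws
#'   from the stationary distribution.
#' @return A list of class `single_channel_sim` with elements `recording` (a
#'   `single_channel_recording`) and `states` (1-based level index per
#'   sample).
#' @export
simulate_single_channel <- function(model, duration = 60,
                                    sample_rate = model$base_rate,
                                    filter_cutoff = 1000, seed = NULL,
                                    init_state = NULL) {
  stopifnot(inherits(model, "gating_model"))
  n <- round(duration * sample_rate)
  if (n < 10) stop("duration * sample_rate must be at least 10 samples")
  if (filter_cutoff >= sample_rate / 2) stop("filter_cutoff must be below Nyquist")
  check_stochastic(model$transition_matrix)
  P <- model$transition_matrix
  if (sample_rate != model$base_rate) {
    fac <- model$base_rate / sample_rate
    if (fac < 1 || abs(fac - round(fac)) > 1e-8)
      stop("sample_rate must divide the model base_rate")
    P <- rescale_transitions(P, fac)
  }
  if (!is.null(seed)) set.seed(seed)
  init <- if (is.null(init_state)) {
    tryCatch(stationary_distribution(P),
             error = function(e) rep(1 / nrow(P), nrow(P)))
  } else {
    stopifnot(init_state >= 1, init_state <= nrow(P))
    as.numeric(seq_len(nrow(P)) == init_state)
  }
  states <- markov_path_cpp(P, init, n) + 1L
  raw <- model$level_currents[states] + rnorm(n, 0, model$noise_sd)
  samples <- zero_phase_butterworth(raw, filter_cutoff, sample_rate)
  rec <- single_channel_recording(samples, sample_rate = sample_rate,
                                  filter_cutoff = filter_cutoff,
                                  voltage = model$voltage,
                                  permeant_ion = model$permeant_ion,
                                  genotype = model$genotype)
  structure(list(recording = rec, states = states, model = model),
            class = "single_channel_sim")
}

#' Single-channel recording container
#'
#' @param samples Current samples in pA.
#' @param sample_rate Acquisition rate, Hz.
#' @param filter_cutoff Analogue/anti-alias low-pass cutoff, Hz.
#' @param voltage Holding potential, mV (matrix side relative to cytosolic).
#' @param permeant_ion,genotype Labels.
#' @return An object of class `single_channel_recording`.
#' @export
single_channel_recording <- function(samples, sample_rate, filter_cutoff = NA,
                                     voltage = NA, permeant_ion = "Ca",
                                     genotype = "WT") {
  samples <- as.numeric(samples)
  if (length(samples) < 2) stop("a recording needs at least 2 samples")
  if (any(!is.finite(samples))) stop("recording contains non-finite samples")
  if (sample_rate <= 0) stop("sample_rate must be positive")
  structure(list(samples = samples, sample_rate = sample_rate,
                 filter_cutoff = filter_cutoff, voltage = voltage,
                 permeant_ion = permeant_ion, genotype = genotype),
            class = "single_channel_recording")
}

#' @export
print.single_channel_recording <- function(x, ...) {
  cat(sprintf("single-channel recording: %d samples at %g kHz (%.2f s), %s, %g mV\n",
              length(x$samples), x$sample_rate / 1000,
              length(x$samples) / x$sample_rate, x$permeant_ion, x$voltage))
  invisible(x)
}
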