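#' Whole-mitoplast ramp current model
#'
#' Generative model for inwardly rectifying uniporter currents during a
#' voltage ramp. The open-channel shape suppresses the outward limb (a pore
#' property, independent of MICUs); the amplitude saturates with cytosolic
#' calcium, is potentiated about two-fold by MICUs in WT relative to
#' MICU1-KO, is blocked by cytosolic magnesium with Hill kinetics (optionally
#' competitive with calcium), and supports sodium and manganese as alternate
#' charge carriers. Sodium conduction is blocked by nanomolar calcium (Kd of
#' about 2 nM at the selectivity filter) identically in both genotypes;
#' manganese currents are about 7-fold smaller than calcium currents.
#'
#' @param g_max Maximal chord conductance scale, nS.
#' @param ca_half Half-saturating cytosolic calcium, uM.
#' @param micu_factor WT/KO amplitude multiplier at saturating calcium.
#' @param micu_ec50_uM EC50 of the MICU potentiation in uM (EF-hand
#'   affinity, 0.6 uM).
#' @param mg_block List with `ic50` (uM), `n_h`, and `competitive` (logical;
#'   when TRUE the effective IC50 is `ic50 * (1 + ca_i/ca_half)`).
#' @param na_block_kd Cytosolic calcium Kd blocking the sodium current, nM.
#' @param g_na Sodium-mode conductance scale, nS.
#' @param mn_factor Manganese amplitude relative to calcium.
#' @param rect List with `v_half` and `slope` (mV) of the Boltzmann factor
#'   suppressing the outward limb.
#' @param capacitance Mitoplast membrane capacitance, pF.
#' @param noise_sd Additive Gaussian current noise, pA.
#' @return An object of class `ramp_model`.
#' @export
ramp_model <- function(g_max = 0.3, ca_half = 1000, micu_factor = 2,
                       micu_ec50_uM = 0.6,
                       mg_block = list(ic50 = 149, n_h = 0.9, competitive = TRUE),
                       na_block_kd = 2, g_na = 0.3, mn_factor = 1 / 7,
                       rect = list(v_half = -20, slope = 15),
                       capacitance = 0.4, noise_sd = 1) {
  stopifnot(g_max > 0, ca_half > 0, micu_factor > 0, mg_block$ic50 > 0,
            mg_block$n_h > 0, na_block_kd > 0, g_na > 0, mn_factor > 0,
            capacitance > 0, noise_sd >= 0)
  structure(list(g_max = g_max, ca_half = ca_half, micu_factor = micu_factor,
                 micu_ec50_uM = micu_ec50_uM, mg_block = mg_block,
                 na_block_kd = na_block_kd, g_na = g_na,
                 mn_factor = mn_factor, rect = rect,
                 capacitance = capacitance, noise_sd = noise_sd),
            class = "ramp_model")
}

#' Noise-free ramp current law
#'
#' Evaluates the generating current law of a [ramp_model()] at given voltages
#' and ionic conditions; exposed so analyses can be checked against the exact
#' law.
#'
#' @param model A [ramp_model()].
#' @param voltage Voltages in mV (matrix side relative to cytosolic side).
#' @param ca_i,mg_i Cytosolic free calcium and magnesium, uM.
#' @param permeant Charge carrier: "Ca", "Na" or "Mn".
#' @param genotype "WT" or "MICU1KO".
#' @return Currents in pA (inward negative).
#' @export
ramp_current_law <- function(model, voltage, ca_i = 0, mg_i = 0,
                             permeant = c("Ca", "Na", "Mn"),
                             genotype = c("WT", "MICU1KO")) {
  permeant <- match.arg(permeant)
  genotype <- match.arg(genotype)
  if (ca_i < 0 || mg_i < 0) stop("concentrations must be non-negative")
  shape <- voltage / (1 + exp((voltage - model$rect$v_half) / model$rect$slope))
  micu <- if (genotype == "WT") {
    1 + (model$micu_factor - 1) * ca_i / (ca_i + model$micu_ec50_uM)
  } else 1
  if (permeant == "Na") {
    # MICUs are calcium-free in the sodium mode: no genotype effect.
    block <- 1 / (1 + (ca_i * 1000) / model$na_block_kd)
    mg_inh <- hill_inhibition_value(mg_i, model$mg_block$ic50, model$mg_block$n_h)
    return(model$g_na * shape * block * mg_inh)
  }
  ic50 <- model$mg_block$ic50
  if (isTRUE(model$mg_block$competitive)) ic50 <- ic50 * (1 + ca_i / model$ca_half)
  mg_inh <- hill_inhibition_value(mg_i, ic50, model$mg_block$n_h)
  act <- ca_i / (ca_i + model$ca_half)
  amp <- model$g_max * act * micu * mg_inh
  if (permeant == "Mn") amp <- amp * model$mn_factor
  amp * shape
}

hill_inhibition_value <- function(conc, ic50, n_h) {
  ifelse(conc <= 0, 1, 1 / (1 + (conc / ic50)^n_h))
}

#' Simulate a whole-mitoplast voltage-ramp sweep
#'
#' Generates one I-V sweep under the standard ramp protocol (-160 to +80 mV)
#' with additive Gaussian noise on top of [ramp_current_law()].
#'
#' @inheritParams ramp_current_law
#' @param model A [ramp_model()].
#' @param protocol List with `v_start`, `v_end` (mV), `duration_s`,
#'   `sample_rate` (Hz) and `hold_ms`: the sweep holds at `v_start` for
#'   `hold_ms` before ramping and at `v_end` after, as in the acquisition
#'   protocol, so the stated readout voltages survive the edge trim of the
#'   analysis.
#' @param ca_matrix_mM Matrix calcium (label only; the outward limb is
#'   suppressed by the pore regardless, which is what the rectification
#'   experiments show).
#' @param seed Integer seed.
#' @return A list of class `ramp_sweep` with `time`, `voltage`, `current`,
#'   `capacitance` and a `condition` list.
#' @export
simulate_ramp <- function(model, ca_i = 0, mg_i = 0,
                          permeant = c("Ca", "Na", "Mn"),
                          genotype = c("WT", "MICU1KO"),
                          protocol = list(v_start = -160, v_end = 80,
                                          duration_s = 0.12, sample_rate = 10000,
                                          hold_ms = 10),
                          ca_matrix_mM = 0, seed = NULL) {
  permeant <- match.arg(permeant)
  genotype <- match.arg(genotype)
  if (ca_i < 0 || mg_i < 0) stop("concentrations must be non-negative")
  if (!is.null(seed)) set.seed(seed)
  hold <- (protocol$hold_ms %||% 10) / 1000
  n_hold <- round(hold * protocol$sample_rate)
  n_ramp <- round(protocol$duration_s * protocol$sample_rate)
  v <- c(rep(protocol$v_start, n_hold),
         seq(protocol$v_start, protocol$v_end, length.out = n_ramp),
         rep(protocol$v_end, n_hold))
  n <- length(v)
  tm <- (seq_len(n) - 1) / protocol$sample_rate
  i <- ramp_current_law(model, v, ca_i, mg_i, permeant, genotype) +
    rnorm(n, 0, model$noise_sd)
  ramp_sweep(tm, v, i, model$capacitance,
             condition = list(permeant = permeant, ca_i = ca_i, mg_i = mg_i,
                              genotype = genotype, ca_matrix_mM = ca_matrix_mM))
}

#' Ramp sweep container
#'
#' @param time Time in s.
#' @param voltage Voltage in mV (matrix minus cytosol).
#' @param current Current in pA (inward negative).
#' @param capacitance Membrane capacitance, pF.
#' @param condition List of recording conditions.
#' @return An object of class `ramp_sweep`.
#' @export
ramp_sweep <- function(time, voltage, current, capacitance, condition = list()) {
  stopifnot(length(time) == length(voltage), length(voltage) == length(current))
  if (capacitance <= 0) stop("capacitance must be positive")
  structure(list(time = time, voltage = voltage, current = current,
                 capacitance = capacitance, condition = condition),
            class = "ramp_sweep")
}

#' Simulate a fast solution-switch current step
#'
#' Emulates the rapid-application experiment: the cytosolic solution is
#' exchanged with an exchange time constant of ~0.4 ms and the current
#' relaxes mono-exponentially to its new level.
#'
#' @param tau_ms Time constant of the relaxation, ms.
#' @param amplitude_pA Steady-state current change, pA (inward negative).
#' @param baseline_pA Pre-switch current, pA.
#' @param direction "activation" (rise after solution on) or "deactivation"
#'   (decay after solution off).
#' @param duration_ms Length of the post-switch record, ms.
#' @param sample_rate Hz.
#' @param noise_sd Gaussian noise, pA.
#' @param seed Integer seed.
#' @return A data.frame with `time_s` and `current_pA`.
#' @export
simulate_fast_application <- function(tau_ms = 0.4, amplitude_pA = -50,
                                      baseline_pA = 0,
                                      direction = c("activation", "deactivation"),
                                      duration_ms = 10, sample_rate = 50000,
                                      noise_sd = 0, seed = NULL) {
  direction <- match.arg(direction)
  stopifnot(tau_ms > 0, duration_ms > 0)
  if (!is.null(seed)) set.seed(seed)
  tm <- seq(0, duration_ms / 1000, by = 1 / sample_rate)
  tau <- tau_ms / 1000
  i <- if (direction == "activation") {
    baseline_pA + amplitude_pA * (1 - exp(-tm / tau))
  } else {
    baseline_pA + amplitude_pA * exp(-tm / tau)
  }
  data.frame(time_s = tm, current_pA = i + rnorm(length(tm), 0, noise_sd))
}
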