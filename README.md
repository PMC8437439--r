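# mcugating

Quantitative analysis of how the MICU subunits gate the mitochondrial
calcium uniporter (MCU), the calcium-selective channel of the inner
mitochondrial membrane. The package is written for electrophysiologists and
mitochondrial physiologists who need reproducible, scriptable versions of
four analysis chains that are usually run through interactive tools:

1. **Single-channel idealization** — hidden Markov model fitting
   (Baum-Welch EM with scaled forward-backward recursions) and Viterbi
   decoding of multi-subconductance unitary currents, yielding level
   amplitudes, occupancies, open probability *P*ₒ and the time-averaged
   unitary current *i* = Σₖ *p*ₖ·*i*ₖ.
2. **Whole-mitoplast ramp metrics** — current densities at stated voltages,
   same-mitoplast current ratios (I_Ca/I_Na, I_Mn/I_Ca), Hill fits of the
   magnesium block `f([Mg]) = 1/(1 + ([Mg]/IC50)^nH)`, one-site calcium
   block of the sodium current, single-exponential activation/deactivation
   kinetics, and a rectification index |I(+80)|/|I(−160)|.
3. **Flux → chord conductance** — indicator calibration (ratiometric
   `[Ca] = K_d·(R−R_min)/(R_max−R)·β` and single-wavelength forms),
   chelator mass-action equilibria, the uptake flux *J* from the 20-s
   linear decline of extramitochondrial calcium, conversion `I = −zFJ`, the
   Nernst potential `E_Ca = (RT/2F)·ln([Ca]ᵢ/[Ca]ₘ)`, and the chord
   conductance `G = I/(ΔΨₘ − E_Ca)`.
4. **Uptake-threshold detection** — zero-phase second-order Butterworth
   smoothing, a derivative criterion (earliest frame above 80% of the
   maximal derivative between baseline and peak), and calibration of the
   time-matched fura-2 ratio to the cytosolic threshold concentration, with
   dish-level ANOVA/Tukey group statistics.

Every recording type has a synthetic generator with known ground truth
(`simulate_single_channel()`, `simulate_ramp()`, `simulate_flux_assay()`,
`simulate_imaging()`), so the whole pipeline is testable by parameter
recovery without any external data. The generators double as the study
conditions: 50 kHz acquisition low-passed at 1 kHz and idealized at
2.5 kHz; sublevels at 80%/60% of the full amplitude; a programmed WT:KO
open-probability contrast with unchanged amplitudes; 3-s imaging frames; a
two-protocol buffered flux assay.

## Worked example

Simulate wild-type and MICU1-knockout-like ensembles (knockout = same
channel with the stationary open probability scaled down 2.5-fold, equal
amplitudes), idealize each record, and compare genotypes:

```r
library(mcugating)

wt <- gating_model()                                   # 0/-2.0/-1.6/-1.2 pA levels
ko <- set_open_probability(wt, open_probability(wt) / 2.5)

analyze <- function(model, seed) {
  sim <- simulate_single_channel(model, duration = 30, seed = seed)
  rec <- resample(sim$recording, 2500)
  fit <- baum_welch_fit(rec, K = 4, seed = seed)
  channel_stats(viterbi_idealize(rec, fit$model), fit$model)
}
stats_wt <- lapply(1:3, function(s) analyze(wt, s))
stats_ko <- lapply(1:3, function(s) analyze(ko, 100 + s))

print(stats_wt[[1]])
#> channel statistics
#>   level currents (pA): 0.001, -1.197, -1.611, -2.004
#>   occupancy:           0.8210, 0.0677, 0.0568, 0.0544
#>   Po = 0.1790, time-averaged current = -0.2809 pA
print(compare_genotypes(stats_wt, stats_ko, stat = "p_open"))
#>   WT: 0.1861 +/- 0.0039 (n = 3)
#>   KO: 0.0788 +/- 0.0013 (n = 3)
#>   ratio WT/KO = 2.360, t = 26.317, p = 0.000474
```

The fitted level currents sit at the programmed −2.0 pA full level and its
80%/60% subconductances; the closed level is at 0. The decoded open
probability differs ~2.4-fold between the ensembles while the amplitudes
match — the gating signature of MICU potentiation.

The imaging chain, on one synthetic wild-type-like cell programmed with a
400 nM uptake threshold:

```r
cal <- indicator_calibration(kd = 224, r_min = 0.3, r_max = 3, beta = 4)
cell <- simulate_imaging(imaging_model(threshold_ca_nM = 400), seed = 2)
print(analyze_imaging_trace(cell, cal))
#> upstroke at frame 56 (t = 165 s), threshold [Ca]i = 416 nM (cutoff 0.0404 Hz)
```

The detector reports the upstroke frame of the mitochondrial signal, the
calibrated cytosolic threshold at that frame, and the smoothing cutoff its
residual analysis selected.

`run_pipeline()` chains these stages (`"single_channel"`, `"flux"`,
`"imaging"`) reproducibly from a seeded config, and
`write_trace_csv()`/`read_trace_csv()` give all four recording types a
common validated CSV format with `# key=value` metadata headers.

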