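---
title: "Methods: quantifying MICU-dependent gating of the mitochondrial calcium uniporter"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying MICU-dependent gating of the mitochondrial calcium uniporter}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mcugating)
```

## The scientific problem

The mitochondrial calcium uniporter complex (MCU) is the calcium-selective
channel of the inner mitochondrial membrane. Its pore (MCU + EMRE subunits)
is regulated by the MICU subunits, EF-hand calcium sensors in the
intermembrane space. The question this package's analyses address is *how*
MICUs regulate the channel: by occluding the pore at resting cytosolic
calcium, or by potentiating its activity once cytosolic calcium rises and
occupies their EF hands. The discriminating measurements are:

1. **Single-channel idealization.** Unitary MCU currents recorded from
   inside-out membrane patches show one closed level and several conducting
   levels, with subconductances near 80% and 60% of the fully open
   amplitude. If MICUs act on gating, knocking out MICU1 should change the
   open probability (Po) but not the unitary amplitudes.
2. **Whole-mitoplast ramp currents.** Macroscopic calcium, sodium and
   manganese currents during a −160 to +80 mV ramp. The sodium current
   (carried when calcium is absent, with MICU EF hands empty) reports the
   conduction pathway independently of MICU potentiation; same-mitoplast
   current ratios cancel channel-number differences. Magnesium blocks the
   pore with Hill kinetics; fast solution exchange probes activation and
   deactivation kinetics; millimolar matrix calcium probes rectification.
3. **Flux-to-conductance inference.** In isolated mitochondria, the decline
   of extramitochondrial calcium gives the uptake flux `J`; with the
   Faraday constant it converts to a current, and the chord-conductance
   relation `I = G (ΔΨ_m − E_Ca)` — with `E_Ca` the Nernst potential from
   the free calcium on both membrane faces — yields the membrane
   conductance `G` as a function of cytosolic calcium.
4. **Imaging threshold detection.** In intact cells, thapsigargin raises
   cytosolic calcium gradually; the mitochondrial indicator starts to rise
   only once cytosolic calcium crosses a threshold. The detector smooths
   the mitochondrial trace with a zero-phase second-order Butterworth
   filter, takes the first frame between baseline and peak whose time
   derivative exceeds 80% of the interval maximum, and time-matches it to
   the calibrated fura-2 ratio.

Every chain is paired with a synthetic-data generator with known ground
truth, so each stage is validated by parameter recovery rather than by
comparison to data that cannot be redistributed.

## Models and assumptions

### Single-channel gating model

A discrete-state Markov chain with one closed state (0 pA) and three
conducting levels at 100/80/60% of the full amplitude (−2.0, −1.6, −1.2 pA
at −120 mV with calcium as the charge carrier). Transition probabilities
are defined **per sampling step at a declared base rate** (50 kHz); when a
trace is analysed at a coarser rate the ground-truth matrix is rescaled by
matrix power (`rescale_transitions()`), which keeps the truth well defined
across rates. Defaults give mean closed dwells of ~20 ms, open dwells of
~5 ms and a stationary Po of ~0.18, producing event densities typical of
the recording condition. White Gaussian noise (0.9 pA SD before filtering)
is added and the trace is low-pass filtered at 1 kHz with a zero-phase
second-order Butterworth filter standing in for the recording hardware's
analogue filter (no filter family is prescribed for synthesis; the
forward-backward Butterworth is the simplest zero-phase choice and its
cutoff is recorded in the metadata).

MICU regulation enters as a Hill-function multiplier (EC50 600 nM — the
EF-hand calcium affinity — coefficient 1, maximal fold 2.5) applied **only
to the closed-to-open transition probabilities**: amplitudes are untouched,
matching the observation that knockout changes Po, not unitary current.
`set_open_probability()` solves for the opening-rate multiplier that
produces an exact target stationary Po, which is how genotype contrasts
(e.g. a programmed WT:KO Po ratio of 2.5) are constructed.

### Idealization (Baum-Welch + Viterbi)

Traces are decimated to 2.5 kHz by non-overlapping block averaging (the
trailing partial block is dropped; non-integer decimation factors are
rejected rather than interpolated). A Gaussian-emission hidden Markov model
with `K` levels is fitted by Baum-Welch EM using scaled forward-backward
recursions (compiled, Rcpp), then the maximum a posteriori state path is
decoded with Viterbi. Numerical choices:

* **Initialization.** The closed level is the amplitude-histogram mode;
  event samples (beyond 3 noise SDs from it) are scanned for `K − 1`
  density peaks. Peak-seeking is preferred over plain k-means because
  filter-smeared transition samples form a shelf between levels that
  k-means chases. Plain k-means and five seeded random perturbations are
  kept as restart candidates; each runs a 20-iteration pilot, the three
  best pilots are refined to convergence.
* **Model selection under correlated noise.** The 1 kHz filter leaves
  residual sample correlation at 2.5 kHz which an iid-Gaussian HMM can
  exploit by splitting a dominant level into sub-states a fraction of a
  noise SD apart — occasionally with *higher* likelihood than the true
  four-level solution. Among converged candidates the fit keeps the best
  likelihood whose level means are separated by more than twice the fitted
  noise SD (states closer than that are not resolvable conductance
  levels), falling back to the overall maximum with a `degenerate` flag.
* **Emission SD** is shared across levels by default (noise is baseline
  dominated in filtered records); per-level SDs are available.
* **Amplitude refinement.** Converged EM means are re-estimated from
  dwell-interior samples of the Viterbi path (both neighbours in the same
  state), because filter-edge samples bias plain EM means toward adjacent
  levels — most visibly for the smallest sublevel, which sits between the
  closed level and the deeper sublevels in amplitude.
* **Dead-time correction.** Transition probabilities are re-estimated from
  the decoded path after merging dwells shorter than the filter rise time
  (`1 + ceiling(0.3 fs/fc)` samples, 2 samples at 2.5 kHz/1 kHz): smeared
  transition samples otherwise appear as spurious one-sample visits to
  amplitude-intermediate levels. Even so, the ignored noise correlation
  leaves a residual dwell-splitting bias that limits transition-probability
  recovery to roughly 0.02–0.03 absolute under the default conditions;
  amplitudes, occupancies and Po are unaffected at their tested tolerances.
* **Convergence**: Δlog-likelihood < 1e-6 per sample, at most 500
  iterations. The closed level of a fitted model is the mean nearest 0 pA,
  ties toward the smaller magnitude.

Per-trace statistics follow from the decoded path: occupancy is the state
frequency, Po is one minus closed occupancy, and the time-averaged unitary
current is the occupancy-weighted sum of level amplitudes (identically the
mean of the reconstructed noise-free trace). Genotype contrasts use
unpaired two-tailed Welch t-tests on per-patch values.

### Ramp currents and fits

The generative current law multiplies a rectifying open-channel shape
`V / (1 + exp((V + 20)/15))` (outward limb suppressed — a pore property,
so matrix calcium produces no outward current in either genotype) by a
saturating calcium activation (half-saturation 1 mM), a MICU potentiation
factor (2-fold at saturating calcium, EC50 0.6 µM, absent in the knockout),
and a Hill magnesium block (IC50 149 µM, coefficient 0.9, optionally
competitive: `IC50_eff = IC50 (1 + [Ca]/ca_half)`). Sodium conduction uses
its own scale, is genotype-independent, and is blocked by cytosolic calcium
with a 2 nM one-site Kd; manganese currents are 1/7 of calcium. Sweeps hold
at −160 mV before and +80 mV after the ramp, as acquisition protocols do, so
the stated readout voltages survive the edge trim.

Analysis reads currents at stated voltages (−160 mV for Ca/Mn, −80 mV for
Na, +80 mV for the outward check) by averaging samples within ±2 mV after
discarding 2 ms at the protocol edges (capacitance transients are removed
without a stated rule in the source workflow; a fixed trim is the simplest
deterministic surrogate). Hill fits fix `f(0) = 1` (currents are normalized
to the zero-blocker level) and use seeded five-start Levenberg-Marquardt;
exponential kinetics fits likewise. Degenerate (zero-amplitude) kinetics
traces are rejected rather than fitted.

### Flux assays and chord conductance

The generator integrates cumulative uptake under the chord-conductance law
with `deSolve`, computing extramitochondrial free calcium from the chelator
mass-action equilibrium at every step; matrix free calcium (200 nM) and the
membrane potential (−160 mV) are treated as clamped over the 35-s record
(matrix buffering; substrate-energized respiration). Two buffer protocols
mirror the assay: boluses ≤ 3 µM use 3 µM Fluo-4 (Kd 0.35 µM) as the only
significant buffer; 4–25 µM boluses use 40 µM EGTA with 1 µM Fluo4-FF
(Kd 9.7 µM) as a low-affinity reporter (the protocol boundary is inclusive
to the first). Fluorescence channels are rendered through the indicator
equilibria — a two-state dye model whose ratio obeys the standard
ratiometric (Grynkiewicz) calibration exactly — plus 0.2% multiplicative
noise per channel, a plate-reader-scale noise level.

The default conductance scale (2e4 nS per mg protein) was chosen once so
that a mid-micromolar bolus declines at a few hundredths of a µM/s,
reproducing the decline rates and `J` magnitudes (~1e-11–1e-10 mol s⁻¹
mg⁻¹) of substrate-energized uptake assays; much smaller values would move
nothing measurable within the 35-s record.

Inference retraces the assay arithmetic: single-wavelength calibration
inverts the indicator signal to free calcium; the buffer equilibrium maps
free to total; the flux is the least-squares slope of total
extramitochondrial calcium over the first 20 s (sign-positive into the
matrix, per mg protein); the matrix fura-2 ratio gives matrix free calcium;
the membrane potential comes in mV or through a monotone TMRM-ratio
calibration table (no dye model is hard-coded, since none is prescribed);
and `G = I/(ΔΨ_m − E_Ca)` with `I = −zFJ` (influx is an inward, negative
current; z = 2, F = 96485 C/mol, 298.15 K default). The Nernst potential is
averaged per-sample over the fit window so the chord relation holds on
window averages even as free calcium declines. Driving forces below 1 mV
are an error (undefined chord). Conductance-versus-calcium curves aggregate
per genotype in log-spaced bins; the genotype crossover is the interpolated
zero of the between-genotype difference on log concentration.

### Imaging thresholds

The generator raises cytosolic calcium from 100 nM toward 1 µM with a
100-s saturating exponential after thapsigargin at 120 s; the mitochondrial
channel rises only after the cytosolic trace crosses the programmed
threshold (onset time is obtained by inverting the ramp), with a 20-s rise
constant and 3-fold gain, sampled at 3-s frames with 0.5% multiplicative
noise — a high-SNR ROI-average regime. A knockout-like cell is programmed
with its threshold at the resting level (no delay).

Detection: F/F0 normalization to the pre-stimulus baseline; zero-phase
second-order Butterworth smoothing; central-difference derivative with edge
frames excluded; earliest frame between baseline end and the global peak
whose derivative exceeds 80% of the interval maximum (ties to the earliest
index). The "optimal" cutoff is not prescribed, so it is selected by
residual analysis — the cutoff where the residual-versus-cutoff curve meets
its extrapolated high-cutoff noise floor — with a fixed 0.03 Hz fallback
for 3-s frame data; the cutoff used is recorded in the result. The manual
inspection step of an interactive workflow is replaced by QC flags
(peak-before-stimulus, criterion-at-boundary, saturated fura ratio, flat
trace as an error). Thresholds are calibrated from the raw fura ratio at
the upstroke frame; `filtfilt`'s zero initial conditions are neutralized by
reflection padding so the zero-phase (no-latency) property actually holds
near edges. Group statistics aggregate cells to dish means first and test
across genotypes with one-way ANOVA plus Tukey, the dish being the
statistical unit.

A known, quantified bias: at 3-s frames the detected upstroke can lag the
true onset by about one frame, so thresholds read slightly high while
cytosolic calcium is rising steeply — ~5–7% at a 400 nM threshold under the
default ramp, worst for thresholds just above resting where the ramp is
steepest. This is inherent to derivative-criterion detection at this frame
rate, not to the implementation.

## What the generators do and do not emulate

The generators reproduce: piecewise-constant Markov gating with filtered
Gaussian noise; subconductance structure; genotype contrasts programmed in
Po only; inward rectification; saturating calcium dependence and Hill
magnesium block of macroscopic currents; buffered calcium decline under a
chord-conductance law; exact indicator equilibria; and delayed sigmoidal
mitochondrial uptake. They do **not** emulate: non-Markov (e.g. power-law)
dwell distributions, which the source data do not characterize; baseline
drift, seal instability or capacitance transients; multi-channel patches;
matrix volume changes, calcium efflux pathways or pH dynamics;
photobleaching beyond what F/F0 removes; or biophysically detailed
permeation (no GHK/PNP). Passing recovery tests therefore demonstrates
correctness of the analysis arithmetic and robustness to the modelled
noise, not robustness to every artefact of real recordings.

## Problem sizes

The test suite fits 20 sixty-second records (50 kHz synthesis, 2.5 kHz
analysis) for amplitude/occupancy/Po recovery, 6 + 6 thirty-second records
per charge carrier for the genotype contrasts, 20 flux assays spanning
0.5–25 µM, 100 + 100 imaging cells with thresholds drawn from 150–800 nM,
200+ random Viterbi instances against exhaustive enumeration (T ≤ 12,
K ≤ 4) and 100 random buffer sets against a bisection oracle. The
acceptance script uses the same conditions at somewhat smaller replicate
counts (4 traces per genotype group, 10 assays, 12 cells per genotype),
which it states in its JSON output as `n`.

## Known limitations

* The iid-emission HMM ignores filter-induced sample correlation (as the
  source workflow does); its visible costs — occasional likelihood
  preference for unresolvable sub-states and residual dwell-splitting —
  are mitigated by the resolvability constraint and dead-time correction
  described above, and the remaining transition-probability bias is
  documented rather than hidden.
* Chelator Kds are apparent values supplied by the user; no pH,
  temperature or ionic-strength corrections are applied.
* The TMRM-ratio-to-potential mapping is a pluggable calibration table;
  absolute potentials are only as good as that table.
* `estimate_flux` assumes the 20-s window is short enough that the flux is
  quasi-constant; with weak buffering and small boluses the window average
  underestimates the initial flux.
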