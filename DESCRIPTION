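Package: mcugating
Title: Gating Analysis of the Mitochondrial Calcium Uniporter
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantitative analysis of MICU-dependent gating of the
    mitochondrial calcium uniporter (MCU) from four kinds of recordings:
    hidden Markov model idealization of multi-subconductance single-channel
    patch-clamp traces (Baum-Welch fitting and Viterbi decoding), whole-
    mitoplast voltage-ramp current metrics with Hill block and exponential
    kinetics fits, chord-conductance inference from calcium flux assays in
    isolated mitochondria (indicator calibration, chelator equilibria,
    Nernst potentials), and a zero-phase-filtered derivative detector for
    the cytosolic calcium threshold of mitochondrial uptake. Every recording
    type has a matching synthetic-data generator with known ground truth so
    each stage can be validated by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    signal,
    minpack.lm,
    deSolve,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
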