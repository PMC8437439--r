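fura224 <- indicator_calibration(kd = 224, r_min = 0.3, r_max = 3, beta = 4)

test_that("F/F0 normalization is gain invariant and anchors the baseline at 1", {
  x <- c(rep(10, 20), seq(10, 30, length.out = 30))
  n1 <- normalize_f0(x, 1:20)
  expect_equal(n1[1:20], rep(1, 20))
  expect_equal(normalize_f0(5 * x, 1:20), n1)
  # a programmed 2x plateau normalizes to 2
  y <- c(rep(50, 10), rep(100, 10))
  expect_equal(normalize_f0(y, 1:10)[20], 2)
})

test_that("zero-phase Butterworth filter has unit DC gain and no phase lag", {
  const <- rep(3.7, 200)
  expect_equal(zero_phase_butterworth(const, 0.05, 1 / 3), const, tolerance = 1e-9)
  # frequency far above cutoff is strongly attenuated
  alt <- rep(c(1, -1), 100)
  sm <- zero_phase_butterworth(alt, 0.01, 1 / 3)
  expect_lt(sd(sm[20:180]), 0.02 * sd(alt))
  # filtering a reversed trace and reversing equals filtering the original
  set.seed(3)
  x <- cumsum(rnorm(300))
  a <- zero_phase_butterworth(x, 0.04, 1 / 3)
  b <- rev(zero_phase_butterworth(rev(x), 0.04, 1 / 3))
  expect_equal(a, b, tolerance = 1e-9)
  # a step's midpoint stays put in time
  step <- c(rep(0, 100), rep(1, 100))
  sm2 <- zero_phase_butterworth(step, 0.03, 1 / 3)
  expect_equal(which.min(abs(sm2 - 0.5)), 100, tolerance = 1)
  expect_error(zero_phase_butterworth(const, 0.2, 1 / 3), "Nyquist")
})

test_that("upstroke detector finds a programmed onset and rejects flat traces", {
  # ideal ramp beginning at frame 40
  y <- c(rep(1, 39), 1 + 0.1 * (1:61))
  det <- detect_upstroke(y, baseline_end = 20)
  expect_lt(abs(det$upstroke_frame - 40), 2)
  # monotone rise from the start: criterion met at the interval boundary
  mono <- 1 + 0.05 * (0:99)
  det2 <- detect_upstroke(mono, baseline_end = 1)
  expect_true("criterion_at_boundary" %in% det2$qc_flags)
  expect_error(detect_upstroke(rep(1, 100), baseline_end = 20), "flat")
})

test_that("noiseless threshold scenarios are recovered through the full pipeline", {
  m <- imaging_model(threshold_ca_nM = 400, noise_frac = 0)
  tr <- simulate_imaging(m, seed = 1)
  truth <- attr(tr, "truth")
  res <- analyze_imaging_trace(tr, m$fura)
  expect_lte(abs(res$upstroke_frame - truth$onset_frame), 1)
  expect_equal(res$threshold_ca_nM, 400, tolerance = 0.1)
  # MICU1-KO-like cell: uptake begins at the resting level
  mko <- imaging_model(threshold_ca_nM = 100, baseline_ca_nM = 100,
                       noise_frac = 0)
  trk <- simulate_imaging(mko, seed = 2)
  resk <- analyze_imaging_trace(trk, mko$fura)
  # onset at the stimulus itself: detection sits on the interval boundary,
  # so allow the worst-case single-frame drift of the rising cytosolic ramp
  expect_lt(resk$threshold_ca_nM, 160)
  expect_lt(resk$upstroke_time_s - attr(trk, "truth")$onset_time_s, 7)
  # no mitochondrial signal propagates a no-upstroke error
  m0 <- imaging_model(mito_gain = 0, noise_frac = 0)
  tr0 <- simulate_imaging(m0, seed = 3)
  expect_error(analyze_imaging_trace(tr0, m0$fura), "flat|upstroke")
})

test_that("detector latency stays within one frame across random noiseless onsets", {
  set.seed(17)
  for (i in 1:50) {
    m <- imaging_model(threshold_ca_nM = runif(1, 150, 800),
                       rise_tau_s = runif(1, 60, 150),
                       mito_tau_s = runif(1, 10, 40),
                       mito_gain = runif(1, 1.5, 4), noise_frac = 0)
    tr <- simulate_imaging(m, seed = 100 + i)
    truth <- attr(tr, "truth")
    res <- analyze_imaging_trace(tr, m$fura)
    expect_lte(abs(res$upstroke_frame - truth$onset_frame), 1)
  }
})

test_that("threshold estimates are invariant to a common fura gain", {
  m <- imaging_model(noise_frac = 0)
  tr <- simulate_imaging(m, seed = 4)
  scaled <- tr
  scaled$f340 <- 3.1 * tr$f340
  scaled$f380 <- 3.1 * tr$f380
  r1 <- analyze_imaging_trace(tr, m$fura)
  r2 <- analyze_imaging_trace(scaled, m$fura)
  expect_equal(r2$threshold_ca_nM, r1$threshold_ca_nM, tolerance = 1e-9)
})

test_that("dish-level group statistics behave on degenerate and toy tables", {
  # identical dish means across genotypes: zero between-group variance
  df <- data.frame(threshold_ca_nM = rep(c(390, 400, 410), 2),
                   dish_id = paste0("d", 1:6),
                   genotype = rep(c("WT", "KO"), each = 3))
  out <- batch_thresholds(df)
  expect_equal(out$anova_p, 1, tolerance = 1e-9)
  # two dishes of identical cells: SEM 0
  df2 <- data.frame(threshold_ca_nM = rep(400, 6),
                    dish_id = rep(c("a", "b"), each = 3),
                    genotype = "WT")
  out2 <- batch_thresholds(df2)
  expect_equal(out2$group_summary$sem, 0)
  # hand-computed one-way ANOVA F statistic on a 3-group toy table
  vals <- list(g1 = c(1, 2, 3), g2 = c(2, 3, 4), g3 = c(6, 7, 8))
  df3 <- data.frame(threshold_ca_nM = unlist(vals),
                    dish_id = paste0("d", 1:9),
                    genotype = rep(names(vals), each = 3))
  gm <- mean(unlist(vals))
  ssb <- 3 * sum((sapply(vals, mean) - gm)^2)
  ssw <- sum(sapply(vals, function(v) sum((v - mean(v))^2)))
  f_hand <- (ssb / 2) / (ssw / 6)
  fit <- aov(threshold_ca_nM ~ genotype, data = df3)
  expect_equal(summary(fit)[[1]][["F value"]][1], f_hand)
  out3 <- batch_thresholds(df3)
  expect_lt(out3$anova_p, 0.01)
  expect_s3_class(out3$tukey, "TukeyHSD")
})
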