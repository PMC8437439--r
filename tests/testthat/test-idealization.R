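test_that("block-average resampling behaves on constant, identity and alternating traces", {
  const <- single_channel_recording(rep(-2, 1000), 50000)
  r <- resample(const, 2500)
  expect_equal(r$samples, rep(-2, 50))
  expect_equal(r$sample_rate, 2500)

  same <- resample(const, 50000)
  expect_identical(same$samples, const$samples)

  alt <- single_channel_recording(rep(c(1, -1), 50), 1000)
  expect_equal(resample(alt, 500)$samples, rep(0, 50))

  expect_error(resample(const, 60000), "exceed")
  expect_error(resample(const, 13000), "integer")
})

test_that("K = 1 fit reduces to the trace mean", {
  rec <- single_channel_recording(rnorm(500, -1.3, 0.2), 2500)
  fit <- baum_welch_fit(rec, K = 1)
  expect_equal(fit$model$means, mean(rec$samples))
  st <- channel_stats(viterbi_idealize(rec, fit$model), fit$model)
  expect_equal(st$occupancy, 1)
})

test_that("forward-backward posteriors are proper distributions", {
  set.seed(2)
  rec <- single_channel_recording(c(rnorm(200, 0, 0.2), rnorm(200, -2, 0.2)), 2500)
  m <- hmm_model(c(0, -2), 0.2, matrix(c(0.95, 0.05, 0.05, 0.95), 2, 2))
  dens <- sapply(1:2, function(k) dnorm(rec$samples, m$means[k], m$sd[k]))
  fb <- mcugating:::forward_backward_cpp(dens, m$trans, m$init)
  expect_lt(max(abs(rowSums(fb$gamma) - 1)), 1e-9)
})

test_that("Baum-Welch recovers the generating model from a simulated trace", {
  m <- gating_model()
  out <- idealize_trace(m, duration = 20, seed = 21)
  fit <- out$fit
  expect_true(all(diff(fit$loglik) > -1e-8))
  truth_means <- sort(m$level_currents)
  fitted <- sort(fit$model$means)
  expect_lt(abs(fitted[4]), 0.05)                       # closed level, pA
  expect_equal(fitted[1:3], truth_means[1:3], tolerance = 0.05)
  # truth transition matrix per 2.5 kHz step, reordered to the fit's
  # canonical level order (closed, then increasing |current|)
  # residual dwell-splitting bias from the filter-induced sample correlation
  # (which the HMM ignores) limits transition recovery to ~0.02-0.03 absolute
  truth_trans <- rescale_transitions(m$transition_matrix, 20)
  ord <- order(abs(m$level_currents))
  expect_lt(max(abs(fit$model$trans - truth_trans[ord, ord])), 0.03)
})

test_that("Viterbi recovers a noiseless two-level step trace exactly", {
  x <- c(rep(0, 40), rep(-2, 30), rep(0, 30))
  rec <- single_channel_recording(x + rnorm(100, 0, 1e-4), 2500)
  m <- hmm_model(c(0, -2), 0.1, matrix(c(0.99, 0.01, 0.01, 0.99), 2, 2))
  ideal <- viterbi_idealize(rec, m)
  expect_identical(ideal$states, c(rep(1L, 40), rep(2L, 30), rep(1L, 30)))
})

test_that("Viterbi agrees with exhaustive enumeration on random small instances", {
  set.seed(99)
  for (i in 1:40) {
    K <- sample(2:4, 1)
    T_ <- sample(4:c(12, 8, 6)[K - 1], 1)
    means <- sort(runif(K, -3, 0))
    sds <- runif(K, 0.1, 0.5)
    A <- matrix(runif(K * K), K, K)
    A <- A / rowSums(A)
    init <- runif(K)
    init <- init / sum(init)
    x <- rnorm(T_, sample(means, T_, replace = TRUE), 0.3)
    m <- hmm_model(means[order(abs(means))], sds[order(abs(means))],
                   A[order(abs(means)), order(abs(means))],
                   init[order(abs(means))])
    ideal <- viterbi_idealize(single_channel_recording(x, 1000), m)
    oracle <- brute_force_viterbi(x, m$means, m$sd, m$trans, m$init)
    expect_identical(ideal$states, as.integer(oracle))
  }
})

test_that("channel statistics follow their defining arithmetic", {
  # occupancy {0.7, 0.3} with open mean -2 -> Po 0.3, i_avg -0.6
  states <- c(rep(1L, 70), rep(2L, 30))
  m <- hmm_model(c(0, -2), 0.1, matrix(c(0.9, 0.1, 0.1, 0.9), 2, 2))
  ideal <- structure(list(states = states, K = 2, resample_rate = 2500),
                     class = "idealized_trace")
  st <- channel_stats(ideal, m)
  expect_equal(st$p_open, 0.3)
  expect_equal(st$i_avg, -0.6)
  expect_equal(sum(st$occupancy), 1)

  all_closed <- structure(list(states = rep(1L, 50), K = 2, resample_rate = 2500),
                          class = "idealized_trace")
  st0 <- channel_stats(all_closed, m)
  expect_equal(st0$p_open, 0)
  expect_equal(st0$i_avg, 0)

  # i_avg equals the mean of the noise-free reconstructed trace
  recon <- m$means[states]
  expect_equal(st$i_avg, mean(recon), tolerance = 1e-12)
})

test_that("i_avg consistency holds on fitted output", {
  out <- idealize_trace(gating_model(), duration = 5, seed = 31)
  st <- out$stats
  expect_equal(st$i_avg, sum(st$occupancy * st$amplitudes), tolerance = 1e-9)
})

test_that("genotype comparison reports ratios and textbook t statistics", {
  same <- compare_genotypes(c(0.2, 0.21, 0.19), c(0.2, 0.21, 0.19))
  expect_equal(same$ratio, 1)
  expect_gt(same$p_value, 0.95)

  a <- c(1, 2, 3)
  b <- c(2, 4, 6)
  cmp <- compare_genotypes(a, b)
  # Welch t statistic computed by hand
  t_hand <- (mean(a) - mean(b)) / sqrt(var(a) / 3 + var(b) / 3)
  expect_equal(cmp$t_statistic, t_hand)
  expect_equal(cmp$ratio, 0.5)

  expect_error(compare_genotypes(1, c(1, 2)), "at least 2")
})
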