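# Independent oracles used by the tests. These deliberately avoid the
# package's own implementations of the quantities they check.

# Stationary distribution by brute-force power iteration.
power_iteration_stationary <- function(P, iters = 10000, tol = 1e-14) {
  v <- rep(1 / nrow(P), nrow(P))
  for (i in seq_len(iters)) {
    v2 <- as.numeric(v %*% P)
    if (max(abs(v2 - v)) < tol) return(v2)
    v <- v2
  }
  v
}

# Exhaustive Viterbi: scores every one of the K^T state paths.
brute_force_viterbi <- function(x, means, sds, trans, init) {
  K <- length(means)
  T_ <- length(x)
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), T_)))
  logdens <- sapply(seq_len(K), function(k) dnorm(x, means[k], sds[k], log = TRUE))
  lt <- log(trans)
  li <- log(init)
  scores <- li[paths[, 1]] + logdens[cbind(1, paths[, 1])]
  for (t in 2:T_) {
    scores <- scores + lt[cbind(paths[, t - 1], paths[, t])] +
      logdens[cbind(t, paths[, t])]
  }
  as.integer(paths[which.max(scores), ])
}

# Free calcium by naive bisection on the conservation equation.
bisect_free_ca <- function(total, totals, kds, iters = 200) {
  g <- function(f) f + sum(totals * f / (f + kds)) - total
  lo <- 0
  hi <- total
  for (i in seq_len(iters)) {
    mid <- (lo + hi) / 2
    if (g(mid) > 0) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

# Shared fixture: a WT-like gating model and its Po-matched knockout
# counterpart with a programmed open-probability ratio.
fixture_genotype_models <- function(po_ratio = 2.5) {
  wt <- gating_model()
  ko <- set_open_probability(wt, open_probability(wt) / po_ratio)
  ko$genotype <- "MICU1KO"
  list(wt = wt, ko = ko)
}

# Run the full single-channel analysis chain on one simulated trace.
idealize_trace <- function(model, duration, seed, K = 4) {
  sim <- simulate_single_channel(model, duration = duration, seed = seed)
  rec <- resample(sim$recording, 2500)
  fit <- baum_welch_fit(rec, K = K, seed = seed)
  ideal <- viterbi_idealize(rec, fit$model)
  list(sim = sim, rec = rec, fit = fit, ideal = ideal,
       stats = channel_stats(ideal, fit$model))
}

# Scratch directory for file round-trip tests.
local_test_dir <- function() {
  d <- tempfile("mcugating-test-")
  dir.create(d)
  d
}
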