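#' Resample a single-channel recording by block averaging
#'
#' Decimates the trace to `target_rate` by averaging non-overlapping blocks of
#' samples; a trailing partial block is dropped. The decimation factor must be
#' an integer (within 1e-8); other rates are rejected rather than
#' interpolated, so the variance reduction of the averaging step is exact.
#'
#' @param rec A [single_channel_recording()].
#' @param target_rate Target rate in Hz, at most `rec$sample_rate`.
#' @return A `single_channel_recording` at the new rate.
#' @export
resample <- function(rec, target_rate) {
  stopifnot(inherits(rec, "single_channel_recording"))
  if (target_rate > rec$sample_rate) stop("target_rate must not exceed the sample rate")
  fac <- rec$sample_rate / target_rate
  if (abs(fac - round(fac)) > 1e-8)
    stop("sample_rate / target_rate must be an integer decimation factor")
  fac <- round(fac)
  if (fac == 1) return(rec)
  n <- (length(rec$samples) %/% fac) * fac
  m <- colMeans(matrix(rec$samples[seq_len(n)], nrow = fac))
  out <- rec
  out$samples <- m
  out$sample_rate <- target_rate
  out
}

#' Conductance-level hidden Markov model
#'
#' @param means Current of each level in pA; level 1 must be the level
#'   nearest 0 pA (the closed state).
#' @param sd Emission standard deviation, shared (length 1) or per level.
#' @param trans Row-stochastic transition matrix per resampled step.
#' @param init Initial state distribution.
#' @return An object of class `hmm_model`.
#' @export
hmm_model <- function(means, sd, trans, init = rep(1 / length(means), length(means))) {
  K <- length(means)
  stopifnot(K >= 1, length(sd) %in% c(1, K), all(sd > 0))
  if (K > 1) {
    check_stochastic(trans, K, tol = 1e-10)
    if (which.min(abs(means)) != 1)
      stop("level 1 must be the mean nearest 0 pA")
  }
  if (abs(sum(init) - 1) > 1e-10 || any(init < 0))
    stop("init must be a probability vector")
  structure(list(K = K, means = means,
                 sd = if (length(sd) == 1) rep(sd, K) else sd,
                 trans = trans, init = init),
            class = "hmm_model")
}

# Canonical level order: closed (nearest 0, ties toward smaller |mean|)
# first, then increasing |mean|.
canonical_order <- function(means) order(abs(means), abs(means))

emission_density <- function(x, model, log = FALSE) {
  K <- model$K
  out <- matrix(0, length(x), K)
  for (k in seq_len(K))
    out[, k] <- dnorm(x, model$means[k], model$sd[k], log = log)
  out
}

#' Fit a conductance-level HMM by Baum-Welch expectation maximization
#'
#' Gaussian-emission HMM fitted with scaled forward-backward recursions.
#' Initial means come from k-means on the (resampled) amplitude distribution
#' plus seeded random restarts; each candidate runs a short pilot and the best
#' pilot likelihood is refined to convergence. The emission standard deviation
#' is shared across levels by default, since the noise of filtered patch
#' records is baseline dominated. The returned model is put in canonical
#' order (closed level first).
#'
#' The log-likelihood trajectory is non-decreasing up to numerical slack; it
#' is returned so this EM guarantee can be checked on every fit.
#'
#' @param rec A (typically resampled) [single_channel_recording()].
#' @param K Number of conductance levels including closed.
#' @param init Optional [hmm_model()] to start from (skips the restart
#'   search).
#' @param max_iter Maximum EM iterations.
#' @param tol Convergence threshold on the per-sample log-likelihood gain.
#' @param n_restarts Random restarts on top of the k-means start.
#' @param shared_sd Share one emission SD across levels.
#' @param refine_amplitudes After convergence, re-estimate the level means
#'   from dwell-interior samples of the Viterbi path (samples whose two
#'   neighbours share their state). The anti-alias filter smears level
#'   transitions over a few samples, which biases plain EM means toward the
#'   adjacent level; interior samples are free of that edge effect. The
#'   transition matrix and emission SD keep their EM estimates.
#' @param seed Seed for k-means and the restarts.
#' @return A list of class `hmm_fit`: `model`, `loglik` (trajectory),
#'   `converged`, `degenerate` (TRUE when two fitted means nearly coincide).
#' @export
baum_welch_fit <- function(rec, K, init = NULL, max_iter = 500, tol = 1e-6,
                           n_restarts = 5, shared_sd = TRUE,
                           refine_amplitudes = TRUE, seed = 1) {
  stopifnot(inherits(rec, "single_channel_recording"), K >= 1)
  x <- rec$samples
  if (K == 1) {
    model <- hmm_model(mean(x), max(sd(x), 1e-12), matrix(1, 1, 1), 1)
    ll <- sum(dnorm(x, model$means, model$sd[1], log = TRUE))
    return(structure(list(model = model, loglik = ll, converged = TRUE,
                          degenerate = FALSE), class = "hmm_fit"))
  }
  starts <- if (!is.null(init)) list(init) else {
    if (!is.null(seed)) set.seed(seed)
    base_means <- closed_aware_means(x, K)
    km <- kmeans(x, centers = K, nstart = 5, iter.max = 50)
    spread <- diff(range(x))
    c(list(start_model(base_means, x), start_model(km$centers[, 1], x)),
      lapply(seq_len(n_restarts), function(i)
        start_model(base_means + rnorm(K, 0, 0.15 * spread / K), x)))
  }
  pilot <- lapply(starts, function(m)
    bw_run(x, m, max_iter = min(20, max_iter), tol = tol, shared_sd = shared_sd))
  ll_pilot <- vapply(pilot, function(f) tail(f$loglik, 1), 0)
  # Refine the three best pilots to convergence. Among the converged fits,
  # prefer the highest likelihood whose level means are separated beyond the
  # fitted noise (filtered records have residual sample correlation that an
  # iid-Gaussian HMM can exploit by splitting a dominant level into
  # sub-states a fraction of the noise SD apart; such states are not
  # resolvable conductance levels). Fall back to the overall maximum if no
  # candidate is resolvable.
  top <- utils::head(order(ll_pilot, decreasing = TRUE), 3)
  fits <- lapply(top, function(i)
    bw_run(x, pilot[[i]]$model, max_iter = max_iter, tol = tol,
           shared_sd = shared_sd, loglik0 = pilot[[i]]$loglik))
  lls <- vapply(fits, function(f) tail(f$loglik, 1), 0)
  resolvable <- vapply(fits, function(f)
    min(diff(sort(f$model$means))) > 2 * max(f$model$sd), FALSE)
  fit <- if (any(resolvable)) {
    fits[resolvable][[which.max(lls[resolvable])]]
  } else {
    fits[[which.max(lls)]]
  }
  # canonical order, closed level first
  ord <- canonical_order(fit$model$means)
  m <- fit$model
  fit$model <- hmm_model(m$means[ord], m$sd[ord], m$trans[ord, ord, drop = FALSE],
                         m$init[ord] / sum(m$init[ord]))
  if (refine_amplitudes) {
    st <- viterbi_cpp(emission_density(x, fit$model, log = TRUE),
                      log(pmax(fit$model$trans, 1e-300)),
                      log(pmax(fit$model$init, 1e-300))) + 1L
    n <- length(st)
    mid <- 2:(n - 1)
    interior <- st[mid - 1] == st[mid] & st[mid + 1] == st[mid]
    means <- fit$model$means
    for (k in seq_len(K)) {
      xs <- x[mid][interior & st[mid] == k]
      if (length(xs) >= 20) means[k] <- mean(xs)
    }
    trans <- fit$model$trans
    # transition probabilities from the dead-time-corrected decoded path:
    # dwells shorter than the filter rise time are artefacts of the
    # anti-alias smearing and would inflate the exit rates of
    # amplitude-intermediate levels
    if (is.finite(rec$filter_cutoff)) {
      d <- 1 + ceiling(0.3 * rec$sample_rate / rec$filter_cutoff)
      stc <- apply_dead_time(st, d)
      counts <- table(factor(stc[-n], levels = seq_len(K)),
                      factor(stc[-1], levels = seq_len(K)))
      rs <- rowSums(counts)
      ok <- rs > 0
      trans[ok, ] <- as.matrix(counts[ok, , drop = FALSE]) / rs[ok]
    }
    ord2 <- canonical_order(means)
    fit$model <- hmm_model(means[ord2], fit$model$sd[ord2],
                           trans[ord2, ord2, drop = FALSE],
                           fit$model$init[ord2] / sum(fit$model$init[ord2]))
  }
  fit$degenerate <- min(diff(sort(fit$model$means))) <
    0.05 * max(diff(range(fit$model$means)), 1e-12)
  if (fit$degenerate)
    warning("fitted means nearly coincide; K may exceed the number of resolvable levels")
  structure(fit, class = "hmm_fit")
}

# Initial level means from the amplitude histogram: the dominant closed peak
# sits at the histogram mode; opening events are the samples well clear of
# it, and their density peaks mark the conducting levels (filter-smeared
# transition samples form a low shelf between peaks that k-means would chase
# but mode-seeking ignores). Falls back to k-means when there are too few
# events or too few resolved peaks.
closed_aware_means <- function(x, K) {
  d <- stats::density(x, n = 512)
  mode <- d$x[which.max(d$y)]
  sd0 <- stats::mad(x[abs(x - mode) < 2 * stats::mad(x)], center = mode)
  ev <- x[abs(x - mode) > 3 * max(sd0, 1e-12)]
  if (length(ev) >= 10 * (K - 1)) {
    de <- stats::density(ev, n = 512)
    y <- de$y
    is_peak <- which(y > c(y[-1], -Inf) & y >= c(-Inf, y[-length(y)]))
    is_peak <- is_peak[order(y[is_peak], decreasing = TRUE)]
    # drop peaks closer than the noise scale to an already accepted one
    sel <- integer(0)
    for (p in is_peak) {
      if (all(abs(de$x[p] - de$x[sel]) > 2 * sd0)) sel <- c(sel, p)
      if (length(sel) == K - 1) break
    }
    if (length(sel) == K - 1) return(c(mode, de$x[sel]))
    km <- kmeans(ev, centers = K - 1, nstart = 10, iter.max = 50)
    return(c(mode, km$centers[, 1]))
  }
  kmeans(x, centers = K, nstart = 10, iter.max = 50)$centers[, 1]
}

start_model <- function(means, x) {
  K <- length(means)
  # tie-break the closed assignment before fitting so validation passes
  ord <- canonical_order(means)
  means <- means[ord]
  trans <- matrix(0.05 / (K - 1), K, K)
  diag(trans) <- 0.95
  hmm_model(means, max(sd(x) / 2, 1e-6), trans)
}

bw_run <- function(x, model, max_iter, tol, shared_sd, loglik0 = numeric(0)) {
  T_ <- length(x)
  ll_trace <- loglik0
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    dens <- emission_density(x, model)
    dens <- pmax(dens, 1e-300)
    fb <- forward_backward_cpp(dens, model$trans, model$init)
    ll_trace <- c(ll_trace, fb$loglik)
    g <- fb$gamma
    w <- colSums(g)
    means <- colSums(g * x) / w
    if (shared_sd) {
      v <- sum(g * (outer(x, means, "-"))^2) / T_
      sds <- rep(sqrt(max(v, 1e-12)), model$K)
    } else {
      sds <- sqrt(pmax(colSums(g * (outer(x, means, "-"))^2) / w, 1e-12))
    }
    trans <- fb$xi / pmax(rowSums(fb$xi), 1e-300)
    trans <- trans / rowSums(trans)
    init <- pmax(g[1, ], 1e-12)
    init <- init / sum(init)
    model <- structure(list(K = model$K, means = means, sd = sds,
                            trans = trans, init = init), class = "hmm_model")
    n_ll <- length(ll_trace)
    if (n_ll > 1 && (ll_trace[n_ll] - ll_trace[n_ll - 1]) / T_ < tol) {
      converged <- TRUE
      break
    }
  }
  list(model = model, loglik = ll_trace, converged = converged)
}

#' Merge unresolvably short dwells in a decoded state path
#'
#' Dwells shorter than `d` samples are below the rise time of the recording
#' filter and cannot represent genuine sojourns; each is merged into the
#' preceding dwell (the first run merges forward). Used when transition
#' probabilities are re-estimated from a decoded path.
#'
#' @param states Integer state path.
#' @param d Minimum resolvable dwell in samples.
#' @return Corrected state path of the same length.
#' @export
apply_dead_time <- function(states, d) {
  if (d <= 1) return(states)
  r <- rle(as.integer(states))
  repeat {
    short <- which(r$lengths < d)
    if (length(short) == 0 || length(r$lengths) == 1) break
    i <- short[1]
    j <- if (i == 1) 2 else i - 1
    r$values[i] <- r$values[j]
    r <- rle(inverse.rle(r))
  }
  inverse.rle(r)
}

#' Idealize a recording with the Viterbi algorithm
#'
#' Classifies every sample to a conductance level by maximum a posteriori
#' decoding under the fitted HMM.
#'
#' @param rec A [single_channel_recording()] at the rate the model was fit at.
#' @param model An [hmm_model()].
#' @return A list of class `idealized_trace` with `states` (1-based level
#'   index per sample) and `resample_rate`.
#' @export
viterbi_idealize <- function(rec, model) {
  stopifnot(inherits(rec, "single_channel_recording"), inherits(model, "hmm_model"))
  if (any(rowSums(model$trans) <= 0)) stop("degenerate model: zero-probability row")
  logdens <- emission_density(rec$samples, model, log = TRUE)
  lt <- log(pmax(model$trans, 1e-300))
  li <- log(pmax(model$init, 1e-300))
  states <- viterbi_cpp(logdens, lt, li) + 1L
  structure(list(states = states, K = model$K,
                 resample_rate = rec$sample_rate),
            class = "idealized_trace")
}

#' Per-level statistics of an idealized trace
#'
#' Occupancy probabilities are the state frequencies of the decoded path; the
#' open probability is one minus the closed-level occupancy, and the
#' time-averaged unitary current is the occupancy-weighted sum of the level
#' amplitudes (identically the mean of the noise-free reconstructed trace).
#'
#' @param ideal An [viterbi_idealize()] result.
#' @param model The [hmm_model()] used for decoding.
#' @return A list of class `channel_stats`: `amplitudes`, `occupancy`,
#'   `p_open`, `i_avg`.
#' @export
channel_stats <- function(ideal, model) {
  stopifnot(inherits(ideal, "idealized_trace"), inherits(model, "hmm_model"))
  if (length(ideal$states) == 0) stop("empty idealized path")
  occ <- tabulate(ideal$states, nbins = model$K) / length(ideal$states)
  closed <- which.min(abs(model$means))
  structure(list(amplitudes = model$means, occupancy = occ,
                 p_open = 1 - occ[closed],
                 i_avg = sum(occ * model$means)),
            class = "channel_stats")
}

#' @export
print.channel_stats <- function(x, ...) {
  cat("channel statistics\n")
  cat("  level currents (pA):", paste(sprintf("%.3f", x$amplitudes), collapse = ", "), "\n")
  cat("  occupancy:          ", paste(sprintf("%.4f", x$occupancy), collapse = ", "), "\n")
  cat(sprintf("  Po = %.4f, time-averaged current = %.4f pA\n", x$p_open, x$i_avg))
  invisible(x)
}

#' Compare a per-channel statistic between two genotype groups
#'
#' Reports group means with SEM, the ratio of means, and a two-tailed
#' unpaired t-test, the standard summary for WT versus knockout contrasts of
#' open probability or amplitude.
#'
#' @param group_a,group_b Numeric vectors (one value per patch), or lists of
#'   [channel_stats()] from which `stat` is extracted.
#' @param stat Field to extract when channel-stats lists are given
#'   (`"p_open"`, `"i_avg"`, or `"full_amplitude"` for the largest-|i| level).
#' @param labels Group labels.
#' @return A list of class `genotype_comparison` with per-group `n`, `mean`,
#'   `sem`, plus `ratio` (a/b) and `p_value`.
#' @export
compare_genotypes <- function(group_a, group_b, stat = "p_open",
                              labels = c("WT", "KO")) {
  extract <- function(g) {
    if (is.numeric(g)) return(g)
    vapply(g, function(s) {
      if (stat == "full_amplitude") s$amplitudes[which.max(abs(s$amplitudes))]
      else s[[stat]]
    }, 0)
  }
  a <- extract(group_a)
  b <- extract(group_b)
  if (length(a) < 2 || length(b) < 2) stop("each group needs at least 2 recordings for SEM")
  tt <- t.test(a, b, var.equal = FALSE)
  structure(list(labels = labels, n = c(length(a), length(b)),
                 mean = c(mean(a), mean(b)),
                 sem = c(sd(a) / sqrt(length(a)), sd(b) / sqrt(length(b))),
                 ratio = mean(a) / mean(b),
                 t_statistic = unname(tt$statistic),
                 p_value = tt$p.value),
            class = "genotype_comparison")
}

#' @export
print.genotype_comparison <- function(x, ...) {
  for (i in 1:2)
    cat(sprintf("  %s: %.4f +/- %.4f (n = %d)\n", x$labels[i], x$mean[i],
                x$sem[i], x$n[i]))
  cat(sprintf("  ratio %s/%s = %.3f, t = %.3f, p = %.3g\n", x$labels[1],
              x$labels[2], x$ratio, x$t_statistic, x$p_value))
  invisible(x)
}
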