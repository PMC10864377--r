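# Shared fixtures and independent oracles, all built in code.

# random valid single-colony dataset (n <= 10, T <= 3) for oracle batteries
random_tiny_dataset <- function(n = sample(2:10, 1), T = sample(2:3, 1),
                                p = runif(1, 0.3, 0.9)) {
  repeat {
    h <- matrix(rbinom(n * T, 1L, p), n, T)
    if (all(rowSums(h) > 0L)) break
  }
  capture_dataset(h, colony = rep("A", n))
}

# Brute-force oracle for the constant one-colony closed model: maximize the
# full log-likelihood on a fine (p, f0) grid, transcribing the closed form
# directly from sufficient statistics (independent of the package's
# likelihood code path).
grid_oracle_constant <- function(dataset,
                                 p_grid = seq(0.001, 0.999, by = 0.001),
                                 f0_grid = seq(0, 50, by = 0.01)) {
  h <- dataset$histories
  n <- nrow(h)
  T <- ncol(h)
  x_tot <- sum(h)
  best <- -Inf; best_p <- NA_real_; best_f0 <- NA_real_
  for (f0 in f0_grid) {
    N <- n + f0
    ll <- lgamma(N + 1) - lgamma(f0 + 1) +
      x_tot * log(p_grid) + (T * N - x_tot) * log1p(-p_grid)
    i <- which.max(ll)
    if (ll[i] > best) { best <- ll[i]; best_p <- p_grid[i]; best_f0 <- f0 }
  }
  list(logLik = best, p = best_p, f0 = best_f0)
}

# 1-D grid oracle for the Huggins conditional likelihood (constant p, one
# colony), written from the definition, per-nest and per-occasion.
huggins_grid_oracle <- function(dataset, p_grid = seq(0.001, 0.999, by = 0.001)) {
  h <- dataset$histories
  n <- nrow(h); T <- ncol(h)
  ll <- vapply(p_grid, function(p) {
    pr_hist <- apply(h, 1L, function(y) prod(p^y * (1 - p)^(1 - y)))
    sum(log(pr_hist)) - n * log(1 - (1 - p)^T)
  }, numeric(1))
  i <- which.max(ll)
  list(p = p_grid[i], logLik = ll[i])
}

# Direct per-nest transcription of the full closed log-likelihood for a
# single colony with constant p: loops over records and occasions, no
# sufficient statistics (independent of nll_from_stats).
loglik_direct_constant <- function(dataset, p, f0) {
  h <- dataset$histories
  n <- nrow(h); T <- ncol(h); N <- n + f0
  ll <- lgamma(N + 1) - lgamma(f0 + 1)
  for (i in seq_len(n)) {
    for (t in seq_len(T)) {
      ll <- ll + if (h[i, t] == 1L) log(p) else log(1 - p)
    }
  }
  # never-detected pseudo-individuals: f0 misses at every occasion
  ll + f0 * T * log(1 - p)
}
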