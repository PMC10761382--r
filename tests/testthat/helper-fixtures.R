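# shared fixtures, built in code at test time

# a small cohort reused across tests (seed 1 is the suite's canonical seed)
small_cohort <- function(n = 60, seed = 1, ...) {
  generate_cohort(n = n, seed = seed, ...)
}

# lean pipeline config for structural tests
lean_config <- function(...) {
  run_config(n = 80,
             mcmc = list(chains = 2, iterations = 600, warmup = 200),
             imputation = list(m = 2, sweeps = 4, pmm_k = 5),
             ...)
}

# independent brute-force HDI: scan every pair of sorted draws
brute_force_hdi <- function(draws, mass = 0.95) {
  srt <- sort(draws)
  s <- length(srt)
  w <- ceiling(mass * s)
  best <- c(-Inf, Inf)
  for (i in seq_len(s - w + 1)) {
    j <- i + w - 1
    if (srt[j] - srt[i] < best[2] - best[1]) best <- c(srt[i], srt[j])
  }
  best
}

# independent Cronbach alpha (naive covariance-matrix form)
naive_alpha <- function(x) {
  C <- stats::cov(x)
  k <- ncol(x)
  k / (k - 1) * (1 - sum(diag(C)) / sum(C))
}

# closed-form normal-inverse-gamma-free posterior for known sigma2
conjugate_posterior <- function(X, y, sigma2, tau = 1) {
  V <- solve(crossprod(X) / sigma2 + diag(1 / tau^2, ncol(X)))
  list(mean = drop(V %*% crossprod(X, y)) / sigma2, cov = V)
}
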