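# small shared helpers

zscore <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0)
    stop("cannot z-score a zero-variance column", call. = FALSE)
  (x - mean(x)) / s
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Equal-probability thresholds for discretizing a standard normal into
# `levels` ordered categories.
likert_thresholds <- function(levels) {
  stopifnot(levels >= 2)
  stats::qnorm(seq_len(levels - 1) / levels)
}

# Pearson correlation of two thresholded standard normals with latent
# correlation rho, via the Hermite expansion of the step function
# g(x) = sum_j 1{x > tau_j}:
#   Cov(g(X), g(Z)) = sum_{k>=1} c_k^2 rho^k / k!,
#   c_k = sum_j phi(tau_j) He_{k-1}(tau_j).
# Var(g) is exact from the (equal) category probabilities. Truncated at
# k = 15, ample for |rho| <= 0.995.
discretized_correlation <- function(rho, levels, kmax = 15L) {
  tau <- likert_thresholds(levels)
  phi <- stats::dnorm(tau)
  # He_k(tau) by the probabilists' recurrence
  He <- matrix(0, nrow = kmax, ncol = length(tau))  # row k holds He_{k-1}
  He[1, ] <- 1
  if (kmax >= 2) He[2, ] <- tau
  if (kmax >= 3) for (k in 3:kmax)
    He[k, ] <- tau * He[k - 1, ] - (k - 2) * He[k - 2, ]
  ck <- drop(He %*% phi)                     # c_k for k = 1..kmax
  j <- 0:(levels - 1)
  var_g <- mean(j^2) - mean(j)^2             # equal category probabilities
  k <- seq_len(kmax)
  sum(ck^2 * rho^k / factorial(k)) / var_g
}

# Invert discretized_correlation: latent rho giving a target observed
# inter-item correlation after thresholding into `levels` categories.
latent_rho_for_target <- function(target_r, levels) {
  if (target_r <= 0) return(0)
  upper <- 0.9995
  if (discretized_correlation(upper, levels) < target_r)
    stop("infeasible inter-item correlation ", signif(target_r, 3),
         " for ", levels, "-level items", call. = FALSE)
  stats::uniroot(function(r) discretized_correlation(r, levels) - target_r,
                 lower = 0, upper = upper, tol = 1e-9)$root
}

# Inter-item correlation implied by Cronbach's alpha for k parallel items.
alpha_to_interitem_r <- function(alpha, k) {
  r <- alpha / (k - alpha * (k - 1))
  if (!is.finite(r) || r <= 0 || r >= 1)
    stop("infeasible target alpha ", alpha, " for ", k, " items",
         call. = FALSE)
  r
}

write_csv_plain <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
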