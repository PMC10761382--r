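#' Split-chain Gelman-Rubin convergence diagnostic
#'
#' The classic (not rank-normalized) potential-scale-reduction statistic,
#' computed on split chains: each chain is halved, giving `2 * n_chains`
#' sequences of length `n = n_iter / 2`; with `W` the mean within-sequence
#' variance and `B = n * Var(sequence means)`,
#' `Rhat = sqrt(((n - 1)/n * W + B/n) / W)`. Values near 1 indicate the
#' chains agree on the posterior; the convergence bound used throughout is
#' 1.005.
#'
#' @param post A `ts_posterior` from [gibbs_fit()], or a draws matrix
#'   (iterations x chains) for a single parameter.
#' @param threshold Convergence bound on the maximum Rhat (default 1.005).
#' @return List of class `convergence_report`: `r_hat` (named per
#'   parameter), `max_r_hat`, `converged`, `threshold`.
#' @export
compute_rhat <- function(post, threshold = 1.005) {
  mats <- if (inherits(post, "ts_posterior")) {
    stats::setNames(lapply(post$parameters, function(pp) post$draws[, , pp]),
                    post$parameters)
  } else {
    list(parameter = as.matrix(post))
  }
  r_hat <- vapply(mats, split_rhat_matrix, numeric(1))
  max_r <- max(r_hat)
  structure(list(r_hat = r_hat, max_r_hat = max_r,
                 converged = max_r < threshold, threshold = threshold),
            class = "convergence_report")
}

split_rhat_matrix <- function(draws) {
  draws <- as.matrix(draws)
  n_it <- nrow(draws); n_ch <- ncol(draws)
  if (n_ch < 2) stop("compute_rhat needs >= 2 chains", call. = FALSE)
  if (n_it < 4) stop("compute_rhat needs >= 4 draws per chain", call. = FALSE)
  half <- n_it %/% 2
  splits <- cbind(draws[seq_len(half), , drop = FALSE],
                  draws[(n_it - half + 1):n_it, , drop = FALSE])
  n <- half
  mns <- colMeans(splits)
  vars <- apply(splits, 2, stats::var)
  W <- mean(vars)
  if (W == 0) stop("degenerate chain: zero within-chain variance", call. = FALSE)
  B <- n * stats::var(mns)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' @export
print.convergence_report <- function(x, ...) {
  cat("max split-Rhat:", format(x$max_r_hat, digits = 5),
      if (x$converged) "(converged," else "(NOT converged,",
      "threshold", x$threshold, ")\n")
  invisible(x)
}

#' Highest density interval from posterior draws
#'
#' The shortest interval containing `ceiling(mass * S)` of the `S` sorted
#' draws, found by a sliding window of that width; ties on width break to
#' the leftmost (first) window. For a unimodal posterior this is the usual
#' HDI.
#'
#' @param draws Numeric vector of posterior draws (>= 100 for a stable
#'   interval; the window must fit inside the draws).
#' @param mass Probability mass in (0, 1), default 0.95.
#' @return Numeric `c(low, high)`.
#' @export
#' @examples
#' compute_hdi(1:100, 0.95)  # c(1, 95): leftmost width-94 window
compute_hdi <- function(draws, mass = 0.95) {
  draws <- draws[is.finite(draws)]
  if (mass <= 0 || mass >= 1) stop("mass must lie in (0,1)", call. = FALSE)
  s <- length(draws)
  if (s < 100) stop("insufficient samples: need >= 100 draws", call. = FALSE)
  w <- ceiling(mass * s)
  if (w > s) stop("window exceeds number of draws", call. = FALSE)
  srt <- sort(draws)
  lo_idx <- seq_len(s - w + 1)
  widths <- srt[lo_idx + w - 1] - srt[lo_idx]
  i <- which.min(widths)          # which.min takes the first minimum
  c(srt[i], srt[i + w - 1])
}
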