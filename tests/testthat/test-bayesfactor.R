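test_that("pr_inclusion maps the published Bayes factors correctly", {
  expect_equal(pr_inclusion(1), 0.5)
  expect_equal(pr_inclusion(3.17), 0.760, tolerance = 5e-4)
  expect_equal(pr_inclusion(36.24), 0.973, tolerance = 5e-4)
  expect_error(pr_inclusion(-1), ">= 0")
  # strictly increasing bijection from [0, Inf) onto [0, 1)
  g <- seq(0, 50, by = 0.25)
  p <- pr_inclusion(g)
  expect_true(all(diff(p) > 0))
  expect_true(all(p >= 0 & p < 1))
  expect_equal(pr_inclusion(Inf), 1)
})

test_that("the no-data Bayes factor is exactly 1 (posterior = prior)", {
  d <- ts_design(matrix(numeric(0), 0, 2,
                        dimnames = list(NULL, c("a", "b"))), numeric(0))
  fit <- gibbs_fit(d, n_chains = 2, n_iter = 2500, warmup = 100, seed = 1)
  bf <- savage_dickey_bf(fit, "a")
  expect_equal(bf$bf10, 1.0, tolerance = 1e-12)  # conditionals ARE the prior
  expect_equal(bf$pr_incl, 0.5, tolerance = 1e-12)
  bf2 <- savage_dickey_bf(fit, "a", estimator = "normal_approx")
  expect_equal(bf2$bf10, 1.0, tolerance = 0.05)
})

test_that("the analytic oracle behaves at its anchor points", {
  expect_equal(analytic_bf_oracle(matrix(numeric(0), 0, 2,
                                         dimnames = list(NULL, c("a", "b"))),
                                  numeric(0), 1, "a"), 1.0)
  # y orthogonal to the tested column: evidence for the null
  set.seed(2)
  x <- stats::rnorm(400)
  z <- stats::rnorm(400)
  y <- z - x * sum(x * z) / sum(x * x)   # residualized: exactly orthogonal
  X <- cbind(a = x)
  expect_lt(analytic_bf_oracle(X, y, sigma2 = 1, "a"), 1)
})

test_that("Savage-Dickey matches the closed-form oracle on random problems", {
  set.seed(3)
  for (r in 1:5) {
    n <- sample(50:200, 1); p <- sample(2:5, 1)
    X <- matrix(stats::rnorm(n * p), n, p,
                dimnames = list(NULL, paste0("b", 1:p)))
    j <- paste0("b", sample(p, 1))
    beta <- stats::rnorm(p, 0, 0.5)
    beta[match(j, colnames(X))] <- stats::rnorm(1, 0, 1 / sqrt(n))
    sigma2 <- stats::runif(1, 0.5, 2)
    y <- drop(X %*% beta) + stats::rnorm(n, sd = sqrt(sigma2))
    fit <- gibbs_fit(ts_design(X, y), n_chains = 4, n_iter = 5000,
                     warmup = 500, seed = 100 + r, sigma2_fixed = sigma2)
    bf_sd <- savage_dickey_bf(fit, j)$bf10
    bf_or <- analytic_bf_oracle(X, y, sigma2, j)
    expect_lt(abs(log(bf_sd) - log(bf_or)), 0.05)
  }
})

test_that("a strong true effect yields decisive Bayes factors", {
  set.seed(4)
  hits <- replicate(100, {
    n <- 411
    x <- stats::rnorm(n)
    y <- 0.5 * x + stats::rnorm(n)
    fit <- gibbs_fit(ts_design(cbind(b = x), y), n_chains = 1, n_iter = 2000,
                     warmup = 200, seed = sample.int(1e6, 1))
    savage_dickey_bf(fit, "b")$bf10 > 10
  })
  expect_gte(mean(hits), 0.95)
})

test_that("evidence accumulates with n and supports the null when true", {
  pr_at_n <- function(n, b, seeds = 12) {
    vapply(seq_len(seeds), function(s) {
      set.seed(7000 + s * 13 + n)
      x <- stats::rnorm(n)
      y <- b * x + stats::rnorm(n)
      fit <- gibbs_fit(ts_design(cbind(v = x), y), n_chains = 1,
                       n_iter = 1500, warmup = 200, seed = s)
      savage_dickey_bf(fit, "v")$pr_incl
    }, numeric(1))
  }
  med_eff <- vapply(c(50, 200, 800), function(n)
    stats::median(pr_at_n(n, b = 0.3)), numeric(1))
  expect_true(all(diff(med_eff) >= 0))
  expect_lt(stats::median(pr_at_n(800, b = 0)), 0.5)
})

test_that("forced covariates and the BF cap are handled", {
  set.seed(8)
  x <- stats::rnorm(300)
  y <- 3 * x + stats::rnorm(300, sd = 0.3)
  X <- cbind(big = x, age = stats::rnorm(300))
  fit <- gibbs_fit(ts_design(X, y), n_chains = 2, n_iter = 1000,
                   warmup = 200, seed = 9)
  expect_error(savage_dickey_bf(fit, "age"), "forced")
  bf <- savage_dickey_bf(fit, "big", bf_cap = 50)
  expect_true(bf$capped)
  expect_equal(bf$bf10, 50)
})

test_that("summarize_coefficients assembles a consistent table", {
  set.seed(10)
  X <- cbind(s1 = stats::rnorm(150), `s1:ts` = stats::rnorm(150),
             age = stats::rnorm(150))
  y <- 0.5 * X[, 1] + stats::rnorm(150)
  d <- ts_design(X, y, roles = c(s1 = "direct", `s1:ts` = "interaction",
                                 age = "forced"))
  fit <- gibbs_fit(d, n_chains = 2, n_iter = 2000, warmup = 300, seed = 11)
  s <- summarize_coefficients(fit)
  expect_equal(s$name, c("s1", "s1:ts", "age"))
  expect_equal(s$role, c("direct", "interaction", "forced"))
  expect_true(all(is.na(s[s$role == "forced", c("bf10", "pr_incl")])))
  expect_true(all(s$hdi_low <= s$mean & s$mean <= s$hdi_high))
  # batched Rao-Blackwell equals the single-coefficient path
  one <- savage_dickey_bf(fit, "s1")
  expect_equal(s$bf10[1], one$bf10, tolerance = 1e-10)
  # credibility agrees with the decision rule applied to the table
  nf <- s[s$role != "forced", ]
  expect_equal(nf$credible, classify_credible(nf))
})
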