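test_that("registry carries one validated entry per instrument", {
  reg <- scale_registry()
  expect_equal(nrow(reg), 38)
  expect_true(all(reg$n_items >= 2))
  expect_true(all(reg$likert_min < reg$likert_max))
  expect_true(all(reg$target_alpha > 0 & reg$target_alpha <= 1))
  expect_setequal(unique(reg$domain_block),
                  c("individual", "family", "interpersonal", "neighborhood"))
  expect_equal(sum(reg$n_items == 2), 3)   # the r-gated two-item scales
})

test_that("default cohort has the study's shape", {
  ch <- generate_cohort(n = 411, seed = 1)
  reg <- scale_registry()
  expect_equal(nrow(ch$participants), 411)
  expect_length(ch$items, nrow(reg))
  for (i in seq_len(nrow(reg))) {
    expect_equal(ncol(ch$items[[reg$name[i]]]) - 1L, reg$n_items[i],
                 info = reg$name[i])
  }
  expect_true(all(ch$participants$age >= 11 & ch$participants$age <= 17))
  expect_true(all(ch$participants$sex %in% 0:1))
  expect_true(all(ch$truth$true_ts > 0))
  # instrument ranges respected after clipping
  expect_true(all(ch$outcomes$anxiety >= 1 & ch$outcomes$anxiety <= 5))
  expect_true(all(ch$outcomes$depression >= 0 & ch$outcomes$depression <= 3))
})

test_that("T/S marginal matches the configured moments", {
  ch <- generate_cohort(n = 20000, seed = 2)
  expect_equal(mean(ch$truth$true_ts), 0.29, tolerance = 0.05)
  expect_equal(stats::sd(ch$truth$true_ts), 0.81, tolerance = 0.12)
  expect_gt(mean((ch$truth$true_ts - 0.29)^3), 0)  # right skew
})

test_that("missing_rate = 0 leaves no missing cells; MCAR rate is honored", {
  ch0 <- small_cohort(missing_rate = 0)
  expect_false(any(vapply(ch0$items, anyNA, logical(1))))
  ch <- generate_cohort(n = 411, seed = 1, missing_rate = 0.1)
  cells <- unlist(lapply(ch$items, function(x) is.na(x[-1])))
  expect_equal(mean(cells), 0.1, tolerance = 0.01)
})

test_that("MAR missingness tracks caregiver education", {
  ch <- generate_cohort(n = 2000, seed = 3, missing_rate = 0.1,
                        missing_mechanism = "MAR", mar_slope = 1)
  miss_by_p <- rowMeans(sapply(ch$items, function(x) rowMeans(is.na(x[-1]))))
  expect_gt(stats::cor(miss_by_p, ch$participants$cg_education), 0.2)
})

test_that("identical seed and config reproduce the cohort exactly", {
  a <- small_cohort()
  b <- small_cohort()
  expect_identical(a$participants, b$participants)
  expect_identical(a$items, b$items)
  expect_identical(a$outcomes, b$outcomes)
  expect_identical(a$truth$true_ts, b$truth$true_ts)
})

test_that("null effect maps yield uncorrelated outcomes at n = 5000", {
  nul <- list(anxiety = default_effects("anxiety", null_effects = TRUE),
              depression = default_effects("depression", null_effects = TRUE))
  ch <- generate_cohort(n = 5000, seed = 4, effects = nul, missing_rate = 0)
  y <- ch$truth$latent_outcomes$anxiety
  r <- abs(apply(ch$truth$predictors_z, 2, stats::cor, y = y))
  expect_lt(max(r), 0.05)
})

test_that("OLS on the true predictors recovers the effect map (n = 5000)", {
  ch <- generate_cohort(n = 5000, seed = 1, missing_rate = 0)
  P <- ch$truth$predictors_z
  for (oc in c("anxiety", "depression")) {
    em <- default_effects(oc)
    b <- stats::lm.fit(P, ch$truth$latent_outcomes[[oc]])$coefficients
    truth <- c(ts = em$ts_effect, em$direct_effects,
               stats::setNames(em$interaction_effects,
                               paste0(names(em$interaction_effects), ":ts")),
               em$covariate_effects[c("age", "sex", "season")])
    expect_lt(max(abs(b[names(truth)] - truth)), 0.03)
  }
})

test_that("realized Cronbach's alpha hits the target across replicates", {
  # targets spanning the supported band, including coarse binary items
  cases <- list(list(k = 4, lmin = 0, lmax = 6, target = 0.60),
                list(k = 10, lmin = 0, lmax = 1, target = 0.75),
                list(k = 8, lmin = 1, lmax = 5, target = 0.86),
                list(k = 9, lmin = 1, lmax = 5, target = 0.95))
  set.seed(11)
  for (cs in cases) {
    alphas <- replicate(200, {
      tab <- telomod:::simulate_scale_items(411, cs$k, cs$lmin, cs$lmax,
                                            cs$target)
      cronbach_alpha(tab)
    })
    expect_equal(mean(alphas), cs$target, tolerance = 0.05,
                 info = paste("target", cs$target))
  }
})

test_that("infeasible reliability targets fail loudly, naming the scale", {
  reg <- scale_registry()[1, ]
  reg$target_alpha <- 0.9999
  reg$likert_max <- reg$likert_min + 1L   # binary items cannot reach .9999
  expect_error(generate_cohort(n = 50, registry = reg,
                               effects = list(), seed = 1),
               reg$name)
})

test_that("unresolvable effect-map scale names are a configuration error", {
  em <- default_effects("anxiety")
  em$direct_effects <- c(no_such_scale = 0.2)
  expect_error(generate_cohort(n = 50, seed = 1,
                               effects = list(anxiety = em)),
               "no_such_scale")
})

test_that("cohort files round-trip through a directory", {
  ch <- small_cohort()
  dir <- withr::local_tempdir()
  write_cohort(ch, dir)
  expect_true(file.exists(file.path(dir, "participants.csv")))
  expect_true(file.exists(file.path(dir, "truth.json")))
  got <- utils::read.csv(file.path(dir, "outcomes.csv"))
  expect_equal(got$anxiety, ch$outcomes$anxiety, tolerance = 1e-8)
  expect_length(list.files(dir, pattern = "^items_"), 38)
})
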