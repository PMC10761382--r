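test_that("alpha equals 1 for parallel items and matches the naive form", {
  shifted <- cbind(1:4, 2:5, 3:6)        # exact linear shifts of one item
  expect_equal(cronbach_alpha(shifted), 1.0, tolerance = 1e-12)
  dup <- matrix(rep(c(2, 5, 3, 4, 1), 4), ncol = 4)
  expect_equal(cronbach_alpha(dup), 1.0, tolerance = 1e-12)
  set.seed(8)
  x <- matrix(stats::rnorm(60), 12, 5)
  expect_equal(cronbach_alpha(x), naive_alpha(x), tolerance = 1e-12)
})

test_that("alpha is near zero for independent items", {
  set.seed(9)
  x <- matrix(stats::rnorm(2000 * 5), 2000, 5)
  expect_lt(abs(cronbach_alpha(x)), 0.1)
})

test_that("alpha recovery at the published PROMIS reliability", {
  set.seed(10)
  alphas <- replicate(200,
    cronbach_alpha(telomod:::simulate_scale_items(411, 8, 1, 5, 0.86)))
  expect_equal(mean(alphas), 0.86, tolerance = 0.05)
})

test_that("alpha preconditions are enforced", {
  expect_error(cronbach_alpha(cbind(1:5, 2:6)), ">= 3 items")
  expect_error(cronbach_alpha(matrix(1, 5, 3)), "zero total-score variance")
  expect_error(cronbach_alpha(matrix(1:6, 2, 3)), ">= 3 participants")
})

test_that("score_scale aggregates and gates as published", {
  items <- data.frame(participant_id = c("a", "b"),
                      item1 = c(1, 2), item2 = c(1, 4), item3 = c(1, 3),
                      item4 = c(1, 2), item5 = c(1, 4), item6 = c(1, 3),
                      item7 = c(1, 2), item8 = c(1, 4))
  sc <- score_scale(items, "promis_like")
  expect_equal(unname(sc$scores["a"]), 1.0)   # constant responses score 1
  expect_equal(sc$reliability_type, "alpha")
  sc_sum <- score_scale(items, "promis_like", aggregate = "sum")
  expect_equal(unname(sc_sum$scores["a"]), 8)

  two <- data.frame(participant_id = letters[1:5],
                    item1 = c(1, 3, 2, 4, 5), item2 = c(1, 3, 2, 4, 5))
  sc2 <- score_scale(two, "twin")
  expect_equal(sc2$reliability, 1.0)
  expect_equal(sc2$reliability_type, "r")
  expect_true(sc2$included)
})

test_that("the inclusion gate is strict at its boundaries", {
  set.seed(12)
  items <- data.frame(participant_id = 1:50,
                      telomod:::simulate_scale_items(50, 4, 1, 5, 0.7))
  rel <- score_scale(items, "x")$reliability
  # alpha exactly at the threshold is excluded; just under, included
  expect_false(score_scale(items, "x", alpha_min = rel)$included)
  expect_true(score_scale(items, "x", alpha_min = rel - 1e-9)$included)
  two <- data.frame(participant_id = 1:50,
                    telomod:::simulate_scale_items(50, 2, 1, 5, 0.5))
  r <- score_scale(two, "y")$reliability
  expect_false(score_scale(two, "y", r_min = r)$included)
  expect_true(score_scale(two, "y", r_min = r - 1e-9)$included)
})

test_that("missing handling in scoring follows the waiver contract", {
  items <- data.frame(participant_id = c("a", "b", "c"),
                      item1 = c(1, NA, NA), item2 = c(2, 3, NA),
                      item3 = c(3, 4, NA))
  expect_error(score_scale(items, "s"), "missing")
  sc <- score_scale(items, "s", na_waive = TRUE)
  expect_equal(unname(sc$scores["a"]), 2)
  expect_equal(unname(sc$scores["b"]), 3.5)   # mean of observed items
  expect_true(is.na(sc$scores["c"]))          # all-missing row
})

test_that("season dichotomization matches the published partition", {
  expect_equal(as.character(dichotomize_season("2014-09-01")), "autumn_winter")
  expect_equal(as.character(dichotomize_season("2014-03-01")), "spring_summer")
  expect_equal(as.character(dichotomize_season("2015-02-28")), "autumn_winter")
  # total over all 12 months, 6 in each half
  months <- sprintf("2014-%02d-15", 1:12)
  s <- dichotomize_season(months)
  expect_false(anyNA(s))
  expect_equal(sum(s == "autumn_winter"), 6)
  expect_equal(which(s == "spring_summer"), 3:8)
  expect_error(dichotomize_season("not-a-date"))
})

test_that("reliability_report mirrors per-scale scoring", {
  ch <- small_cohort(n = 120, missing_rate = 0)
  rep <- reliability_report(ch$items)
  expect_equal(nrow(rep), 38)
  one <- score_scale(ch$items$loneliness, "loneliness")
  expect_equal(rep$reliability[rep$scale == "loneliness"], one$reliability)
})
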