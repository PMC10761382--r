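conc5 <- 25 / 2^(0:4)

test_that("standard curve recovers a perfect-doubling series exactly", {
  ct <- 30 - log2(conc5 / 1.5625)
  cv <- fit_standard_curve(conc5, ct, target = "TEL")
  expect_equal(cv$slope, -1 / log10(2), tolerance = 1e-10)
  expect_equal(cv$efficiency, 2.0, tolerance = 1e-10)
  expect_equal(cv$r_squared, 1.0, tolerance = 1e-12)
  # noiseless log-linear data of any slope reproduces slope/intercept
  ct2 <- 31.2 - 3.5 * log10(conc5)
  cv2 <- fit_standard_curve(conc5, ct2)
  expect_equal(cv2$slope, -3.5, tolerance = 1e-10)
  expect_equal(cv2$intercept, 31.2, tolerance = 1e-10)
})

test_that("efficiency formula anchors the published values", {
  # frozen: 10^(1/3.678) = 1.8701950, 10^(1/3.584) = 1.9011564
  eff <- function(slope) fit_standard_curve(conc5, 10 + slope * log10(conc5))$efficiency
  expect_equal(eff(-3.678), 1.8701950, tolerance = 1e-6)
  expect_equal(eff(-3.584), 1.9011564, tolerance = 1e-6)
  expect_equal(round(eff(-3.678), 2), 1.87)
  expect_equal(round(eff(-3.584), 2), 1.90)
})

test_that("standard-curve preconditions are enforced", {
  expect_error(fit_standard_curve(c(25, 12.5), c(20, 21)), "insufficient")
  expect_error(fit_standard_curve(conc5, 10 + 3 * log10(conc5)), "invalid")
  expect_error(fit_standard_curve(c(-1, 1, 2), c(20, 21, 22)), "> 0")
})

test_that("triplicate collapse applies the QC rules", {
  r <- collapse_triplicates(c(20, 20, 20))
  expect_equal(r$mean_ct, 20)
  expect_length(r$qc_flags, 0)
  r <- collapse_triplicates(c(20.0, 20.2, 21.0), qc_range = 0.5)
  expect_equal(r$mean_ct, 20.4)
  expect_true("HIGH_RANGE" %in% r$qc_flags)
  r <- collapse_triplicates(c(20.0, 20.2))
  expect_equal(r$mean_ct, 20.1)
  expect_true("LOW_REPLICATES" %in% r$qc_flags)
  expect_error(collapse_triplicates(numeric(0)), "missing reaction")
})

test_that("T/S ratio matches hand-computed cases", {
  expect_equal(compute_ts_ratio(20, 18, 20, 18, 1.9, 1.8), 1.0)
  expect_equal(compute_ts_ratio(20, 18, 22, 18, 2, 2), 4.0)
  # frozen: 1.87 / 1.90^0.5 = 1.3566406
  expect_equal(compute_ts_ratio(21, 17.5, 22, 18, 1.87, 1.90),
               1.3566406, tolerance = 1e-6)
  expect_error(compute_ts_ratio(NA, 18, 22, 18, 2, 2), "finite")
  expect_error(compute_ts_ratio(20, 18, 22, 18, 2.5, 2), "efficienc")
})

test_that("Pfaffl reduces to 2^(-ddCt) when both efficiencies are 2", {
  set.seed(5)
  for (i in 1:25) {
    cts <- stats::runif(4, 15, 30)    # tel, alb, cal_tel, cal_alb
    ddct <- (cts[1] - cts[3]) - (cts[2] - cts[4])
    expect_equal(compute_ts_ratio(cts[1], cts[2], cts[3], cts[4], 2, 2),
                 2^(-ddct), tolerance = 1e-12)
  }
})

test_that("T/S is monotone in the sample Cts", {
  tel_grid <- seq(18, 26, by = 0.5)
  ts_tel <- sapply(tel_grid, compute_ts_ratio, alb_ct = 18, cal_tel_ct = 22,
                   cal_alb_ct = 18, e_tel = 1.87, e_alb = 1.90)
  expect_true(all(diff(ts_tel) < 0))   # more telomere Ct = less signal
  alb_grid <- seq(14, 22, by = 0.5)
  ts_alb <- sapply(alb_grid, function(a)
    compute_ts_ratio(20, a, 22, 18, 1.87, 1.90))
  expect_true(all(diff(ts_alb) > 0))
})

test_that("synthetic plates carry the published dilution series layout", {
  ch <- small_cohort(n = 20)
  pl <- generate_qpcr_plate(ch$truth$true_ts, seed = 2)
  std <- pl$wells[pl$wells$role == "standard", ]
  expect_setequal(unique(std$concentration), c(25, 12.5, 6.25, 3.125, 1.5625))
  expect_equal(min(std$concentration), 1.5625)
  # triplicates for every sample x target, one calibrator per target
  smp <- pl$wells[pl$wells$role == "sample", ]
  counts <- table(smp$sample_id, smp$target)
  expect_true(all(counts == 3))
  expect_equal(sum(pl$wells$role == "calibrator" & pl$wells$target == "TEL"), 3)
})

test_that("noiseless plates round-trip the true T/S exactly", {
  ch <- small_cohort(n = 25)
  pl <- generate_qpcr_plate(ch$truth$true_ts, noise_sd = 0, seed = 3)
  q <- quantify_plate(pl)
  got <- q$ts[match(names(ch$truth$true_ts), q$ts$sample_id), "ts"]
  expect_lt(max(abs(got / ch$truth$true_ts - 1)), 1e-9)
  # fitted efficiencies equal the generating ones, R^2 = 1
  expect_equal(q$curves$TEL$efficiency, 1.87, tolerance = 1e-9)
  expect_equal(q$curves$ALB$efficiency, 1.90, tolerance = 1e-9)
  expect_equal(q$curves$TEL$r_squared, 1.0, tolerance = 1e-10)
  # calibrator self-ratio is exactly 1
  expect_equal(q$ts$ts[q$ts$sample_id == "CAL"], 1.0)
  # curve mode agrees with calibrator mode on noiseless data
  q2 <- quantify_plate(pl, mode = "curve")
  got2 <- q2$ts[match(names(ch$truth$true_ts), q2$ts$sample_id), "ts"]
  expect_equal(got2, got, tolerance = 1e-9)
})

test_that("plates are deterministic and survive the CSV round trip", {
  ts <- c(a = 0.5, b = 1.2, c = 2.0)
  p1 <- generate_qpcr_plate(ts, seed = 9)
  p2 <- generate_qpcr_plate(ts, seed = 9)
  expect_identical(p1$wells, p2$wells)
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_plate(p1, f1); write_plate(p2, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  back <- read_plate(f1)
  expect_equal(back$wells$Ct, p1$wells$Ct, tolerance = 1e-12)
})

test_that("pinned efficiencies override the fitted curves", {
  ch <- small_cohort(n = 10)
  pl <- generate_qpcr_plate(ch$truth$true_ts, noise_sd = 0, seed = 4)
  q <- quantify_plate(pl, fix_efficiency = c(TEL = 2, ALB = 2))
  expect_equal(unname(q$efficiencies), c(2, 2))
})

test_that("ICC behaves at the three anchor points", {
  set.seed(21)
  x <- stats::rnorm(95)
  expect_equal(compute_icc(x, x), 1.0)
  # permutation null: independent re-pairing drives ICC to ~0
  iccs <- replicate(40, compute_icc(stats::rnorm(95), stats::rnorm(95)))
  expect_lt(abs(mean(iccs)), 0.05)
  expect_true(all(abs(iccs) < 0.35))
  # recovery at the published repeatability (0.62), n = 95 pairs
  est <- replicate(500, {
    tr <- stats::rnorm(95, sd = sqrt(0.62))
    compute_icc(tr + stats::rnorm(95, sd = sqrt(0.38)),
                tr + stats::rnorm(95, sd = sqrt(0.38)))
  })
  expect_equal(mean(est), 0.62, tolerance = 0.05)
  expect_error(compute_icc(1:3, 1:3), "insufficient")
})
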