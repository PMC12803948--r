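test_that("precision flags test the span of the last three estimates", {
  # 55, 54, 53 span exactly 2 %MSO -> precise (inclusive boundary)
  expect_true(precision_flags(c(55, 54, 53))[3])
  expect_false(precision_flags(c(55, 52, 53))[3])
  expect_true(precision_flags(c(50, 50, 50))[3])
  f <- precision_flags(c(60, 55, 53, 53, 52))
  expect_identical(is.na(f), c(TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_identical(f[3:5], c(FALSE, TRUE, TRUE))  # (55,53,53) spans 2
})

test_that("the reference value averages tested intensities of trials 25-30", {
  ints <- c(rep(40, 24), rep(54, 6))
  log <- make_fake_log(rep(54, 30), intensity = ints)
  expect_equal(reference_value(log), 54)

  ints2 <- c(rep(40, 24), 55, 55, 54, 55, 54, 55)
  log2 <- make_fake_log(rep(54, 30), intensity = ints2)
  expect_equal(reference_value(log2), 54.667, tolerance = 1e-4)
  # the running-estimate reading stays available
  expect_equal(reference_value(log2, source = "estimate"), 54)
  expect_error(reference_value(make_fake_log(rep(50, 10))), "only 10")
})

test_that("accuracy flags use a relative +/-5 % band, inclusive", {
  expect_true(accuracy_flags(55, 54.6))   # |0.4| <= 2.73
  expect_false(accuracy_flags(58, 54.6))  # 3.4 > 2.73
  expect_true(accuracy_flags(42, 40))     # boundary: 2.0 <= 2.0
  # absolute-band variant behind the flag
  expect_false(accuracy_flags(47, 40, tol = 5, relative = FALSE))
  expect_true(accuracy_flags(45, 40, tol = 5, relative = FALSE))
})

test_that("convergence is the start of the final satisfied run", {
  # satisfied at 4, broken at 5, maintained from 6
  flags <- c(FALSE, FALSE, FALSE, TRUE, FALSE, TRUE, TRUE, TRUE)
  expect_identical(convergence_trial(flags), 6L)
  expect_identical(convergence_trial(rep(TRUE, 5)), 1L)
  # leading NA positions (precision before trial 3) don't count
  expect_identical(convergence_trial(c(NA, NA, TRUE, TRUE)), 3L)
  expect_identical(convergence_trial(c(TRUE, TRUE, FALSE)), NA_integer_)
})

test_that("the 95 % criterion trial and its curve behave", {
  expect_identical(criterion_trial_at_95(rep(1L, 10))$trial, 1L)
  conv <- c(rep(7L, 95), rep(20L, 5))
  res <- criterion_trial_at_95(conv)
  expect_identical(res$trial, 7L)
  expect_true(all(diff(res$curve) >= 0))
  # sessions that never converge keep the curve below 1
  res2 <- criterion_trial_at_95(c(rep(3L, 90), rep(NA_integer_, 10)))
  expect_identical(res2$trial, NA_integer_)
  expect_equal(max(res2$curve), 0.9)
})

test_that("ICC(2,1) matches the two-way ANOVA decomposition", {
  # perfect agreement with between-subject variance
  expect_equal(icc_2_1(cbind(c(1, 2, 3), c(1, 2, 3))), 1)
  # systematic +1 offset with perfect consistency: hand value 8/9
  m <- cbind(c(1, 3, 5), c(2, 4, 6))
  expect_equal(icc_2_1(m), 8 / 9, tolerance = 1e-12)
  expect_equal(icc_2_1(m), icc_oracle_aov(m), tolerance = 1e-12)
  # exchangeable in the subjects
  expect_equal(icc_2_1(m[c(3, 1, 2), ]), icc_2_1(m))

  set.seed(71)
  for (i in 1:30) {
    n <- sample(3:30, 1)
    mm <- matrix(rnorm(2 * n, mean = 50, sd = 5), ncol = 2)
    expect_equal(icc_2_1(mm), icc_oracle_aov(mm), tolerance = 1e-10)
  }
  expect_warning(res <- icc_2_1(cbind(rep(1, 5), rep(1, 5))),
                 "zero total variance")
  expect_true(is.na(res))
  expect_warning(icc_2_1(cbind(1:2, 2:3)), "fewer than 3")
})

test_that("Sw, RC and SEM follow their defining formulas", {
  expect_equal(within_subject_sd(c(5, 5), c(5, 5)), 0)
  expect_equal(within_subject_sd(c(3, 1), c(1, 3)), sqrt(8 / 4))
  expect_equal(within_subject_sd(c(3, 1), c(1, 3)), 1.41421,
               tolerance = 1e-5)
  # homogeneity of degree 1
  expect_equal(within_subject_sd(3 * c(3, 1), 3 * c(1, 3)),
               3 * within_subject_sd(c(3, 1), c(1, 3)))
  expect_error(within_subject_sd(1:3, 1:2), "same length")

  expect_equal(reproducibility_coefficient(0), 0)
  expect_equal(reproducibility_coefficient(1), 1.96 * sqrt(2))
  expect_equal(reproducibility_coefficient(1), 2.77186, tolerance = 1e-5)
  expect_equal(reproducibility_coefficient(1.41421), 3.91979,
               tolerance = 1e-4)

  expect_equal(standard_error_of_measurement(4, 1), 0)
  expect_equal(standard_error_of_measurement(4, 0), 4)
  expect_equal(standard_error_of_measurement(4, 0.84), 1.6)
  expect_error(standard_error_of_measurement(4, 1.2), "exceed")
})

test_that("Bland-Altman summarises paired differences with 1.96 SD limits", {
  ident <- bland_altman(c(50, 55, 60), c(50, 55, 60))
  expect_equal(ident$mean_diff, 0)
  expect_equal(ident$sd_diff, 0)
  expect_equal(c(ident$loa_lower, ident$loa_upper), c(0, 0))

  set.seed(81)
  a <- rnorm(40, 55, 5); b <- a + rnorm(40, 1, 2)
  ba <- bland_altman(a, b)
  expect_equal(ba$mean_diff, mean(a - b))
  expect_equal(ba$sd_diff, sd(a - b))  # n-1 sample SD
  expect_lt(ba$loa_lower, ba$mean_diff)
  expect_gt(ba$loa_upper, ba$mean_diff)
  # widening the noise widens the limits
  b_noisier <- a + rnorm(40, 1, 6)
  ba2 <- bland_altman(a, b_noisier)
  expect_gt(ba2$loa_upper - ba2$loa_lower, ba$loa_upper - ba$loa_lower)
  expect_error(bland_altman(1, 2), "at least 2")
})

test_that("per-trial reliability handles the perfect-agreement case", {
  cfg <- session_config()
  logs <- lapply(c(40, 48, 55, 63), function(t) {
    make_fake_log(rep(t, 30), config = cfg)
  })
  rep1 <- per_trial_reliability(logs, logs, trials = 1:30)
  expect_s3_class(rep1, "reliability_report")
  expect_equal(nrow(rep1), 30)
  expect_true(all(rep1$icc == 1))
  expect_true(all(rep1$sw == 0))
  expect_true(all(rep1$rc == 0))
  expect_true(all(rep1$sem == 0))
  expect_true(all(rep1$loa_lower <= rep1$loa_upper))
  expect_identical(attr(rep1, "icc_convergence"), 1L)
  # deterministic: identical on recomputation
  expect_identical(rep1, per_trial_reliability(logs, logs, trials = 1:30))
})

test_that("between-day drift lowers between-day ICC relative to within-day", {
  # paired estimates with and without an extra day-level perturbation
  set.seed(91)
  truth <- runif(20, 40, 60)
  session_noise <- function() rnorm(20, 0, 1)
  s1 <- truth + session_noise()
  s2 <- truth + session_noise()                 # same day
  s3 <- truth + rnorm(20, 0, 5) + session_noise()  # other day, drifted
  logs <- function(v) lapply(v, function(t) make_fake_log(rep(t, 30)))
  within <- per_trial_reliability(logs(s1), logs(s2), trials = 30)
  between <- per_trial_reliability(logs(s1), logs(s3), trials = 30)
  expect_gt(within$icc, between$icc)
  expect_gt(between$loa_upper - between$loa_lower,
            within$loa_upper - within$loa_lower)
})
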