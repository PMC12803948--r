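test_that("response probability is the cumulative Gaussian at the threshold", {
  expect_equal(response_probability(50, 50, 3.5), 0.5)
  # one spread above the threshold = standard normal CDF at z = 1
  expect_equal(response_probability(53.5, 50, 3.5), pnorm(1),
               tolerance = 1e-12)
  expect_equal(response_probability(53.5, 50, 3.5), 0.8413447,
               tolerance = 1e-6)
  # far left tail before clipping
  expect_lt(response_probability(0, 50, 3.5, epsilon = 0), 1e-10)
  # clipping keeps probabilities usable in logs
  expect_equal(response_probability(0, 50, 3.5, epsilon = 1e-12), 1e-12)
})

test_that("response probability is strictly increasing and validated", {
  x <- seq(30, 70, by = 0.5)
  p <- response_probability(x, 50, 3.5, epsilon = 0)
  expect_true(all(diff(p) > 0))
  # relative mode: sigma scales with the threshold
  expect_equal(response_probability(50 * 1.07, 50, 0.07, "relative"),
               pnorm(1), tolerance = 1e-12)
  expect_error(response_probability(50, 50, -1), "spread")
  expect_error(response_probability(50, 50, 0), "spread")
})

test_that("negative log-likelihood matches hand-computed terms", {
  # anchors only: both anchor probabilities are ~1, NLL ~ 0
  expect_lt(negative_log_likelihood(numeric(0), logical(0), 50), 1e-10)
  # one success at the threshold adds exactly -log(0.5)
  expect_equal(negative_log_likelihood(50, TRUE, 50), log(2),
               tolerance = 1e-9)
  # direct evaluation of a two-trial case against the closed form
  p60 <- pnorm((60 - 50) / 3.5); p40 <- pnorm((40 - 50) / 3.5)
  manual <- -(log(p60) + log(1 - p40))
  got <- negative_log_likelihood(c(60, 40), c(TRUE, FALSE), 50,
                                 anchors = FALSE)
  expect_equal(got, manual, tolerance = 1e-12)
  expect_error(negative_log_likelihood(50, TRUE, -3), "threshold")
})

test_that("likelihood is mirror-symmetric for absolute spread", {
  set.seed(7)
  for (i in 1:20) {
    ts <- random_trialset()
    t_eval <- runif(1, 30, 70)
    c0 <- 50
    direct <- negative_log_likelihood(ts$intensity, ts$outcome, t_eval,
                                      anchors = FALSE)
    mirrored <- negative_log_likelihood(2 * c0 - ts$intensity,
                                        !ts$outcome, 2 * c0 - t_eval,
                                        anchors = FALSE)
    expect_equal(direct, mirrored, tolerance = 1e-10)
  }
})

test_that("ML fit recovers the symmetric solution and tracks the grid oracle", {
  fit <- pest_mle(c(60, 40), c(TRUE, FALSE))
  expect_s3_class(fit, "pest_mle")
  expect_equal(unname(coef(fit)), 50, tolerance = 1e-3)
  expect_false(fit$fallback)

  # anchors only: the likelihood of the two boundary pseudo-trials is
  # symmetric about 50, so the minimiser sits there
  empty <- pest_mle(numeric(0), logical(0))
  oracle <- grid_search_threshold(numeric(0), logical(0),
                                  resolution = 0.01)
  expect_equal(empty$threshold, oracle$threshold, tolerance = 0.02)
  expect_equal(empty$threshold, 50, tolerance = 1e-3)

  # a lone success pulls the threshold below the tested intensity
  lone <- grid_search_threshold(50, TRUE, resolution = 0.01)
  expect_lt(lone$threshold, 50)
  expect_equal(pest_mle(50, TRUE)$threshold, lone$threshold,
               tolerance = 0.02)
})

test_that("optimizer agrees with the exhaustive grid oracle on random data", {
  set.seed(13)
  for (i in 1:40) {
    ts <- random_trialset()
    fit <- pest_mle(ts$intensity, ts$outcome)
    oracle <- grid_search_threshold(ts$intensity, ts$outcome,
                                    resolution = 0.01)
    expect_equal(fit$threshold, oracle$threshold, tolerance = 0.1)
  }
})

test_that("grid refinement changes the argmin by at most the coarse step", {
  set.seed(5)
  ts <- random_trialset()
  coarse <- grid_search_threshold(ts$intensity, ts$outcome,
                                  resolution = 1)
  fine <- grid_search_threshold(ts$intensity, ts$outcome,
                                resolution = 0.01)
  expect_lte(abs(coarse$threshold - fine$threshold), 1)
})

test_that("adding a success never raises, a failure never lowers, the estimate", {
  set.seed(17)
  for (i in 1:25) {
    ts <- random_trialset()
    base <- pest_mle(ts$intensity, ts$outcome)$threshold
    x_new <- sample(20:80, 1)
    with_success <- pest_mle(c(ts$intensity, x_new),
                             c(ts$outcome, TRUE))$threshold
    with_failure <- pest_mle(c(ts$intensity, x_new),
                             c(ts$outcome, FALSE))$threshold
    expect_lte(with_success, base + 1e-4)
    expect_gte(with_failure, base - 1e-4)
  }
})

test_that("fit methods behave like a standard modelling object", {
  set.seed(2)
  ts <- random_trialset()
  fit <- pest_mle(ts$intensity, ts$outcome)

  expect_named(coef(fit), "threshold")
  expect_equal(predict(fit, newdata = fit$threshold), 0.5,
               tolerance = 1e-9)
  expect_equal(as.numeric(logLik(fit)), -fit$nll)
  expect_length(residuals(fit), length(ts$intensity))
  expect_true(all(abs(residuals(fit)) <= 1))
  sims <- simulate(fit, nsim = 3, seed = 1)
  expect_equal(dim(sims), c(length(ts$intensity), 3L))
  expect_output(print(summary(fit)), "threshold")

  # formula interface is a thin wrapper over the default method
  df <- data.frame(intensity = ts$intensity, outcome = ts$outcome)
  fit2 <- pest_mle(outcome ~ intensity, data = df)
  expect_equal(fit2$threshold, fit$threshold, tolerance = 1e-9)
})

test_that("degenerate inputs are handled explicitly", {
  expect_error(pest_mle(c(40, 60), TRUE), "length")
  expect_error(pest_mle(120, TRUE), "MSO")
  expect_warning(pest_mle(c(40, 60), c(TRUE, TRUE), anchors = FALSE),
                 "monotone")
})
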