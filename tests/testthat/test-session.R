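test_that("initial intensity is uniform on 20-60 and reproducible", {
  cfg <- session_config()
  set.seed(1)
  draws <- replicate(1e4, initial_intensity(cfg))
  expect_true(all(draws >= 20 & draws <= 60))
  expect_setequal(unique(draws), 20:60)
  # chi-squared test of uniformity over the 41 values
  expect_gt(chisq.test(table(factor(draws, levels = 20:60)))$p.value,
            0.01)
  set.seed(99); a <- initial_intensity(cfg)
  set.seed(99); b <- initial_intensity(cfg)
  expect_identical(a, b)
})

test_that("next intensity rounds half-away-from-zero and clamps to the device", {
  expect_equal(next_intensity(55.4), 55)
  expect_equal(next_intensity(55.5), 56)
  expect_equal(next_intensity(54.5), 55)
  expect_equal(next_intensity(102.3), 100)  # capped at device max
  expect_equal(next_intensity(0.2), 1)      # lower clamp
  cfg5 <- session_config(intensity_resolution = 0.5)
  expect_equal(next_intensity(55.25, cfg5), 55.5)
})

test_that("a session against a step subject converges onto the step", {
  step_subject <- function(x) x >= 50
  log <- run_session(step_subject, session_config(seed = 11))
  expect_s3_class(log, "rmt_session")
  expect_equal(nrow(log$trials), 30)
  expect_false(log$truncated)
  expect_lt(abs(log$trials$estimate[30] - 50), 1)
  # running estimates replay exactly from the recorded trial sequence
  replay <- running_estimates(log$trials$intensity, log$trials$outcome,
                              log$config)
  expect_equal(replay, log$trials$estimate, tolerance = 1e-6)
})

test_that("a subject that never responds drives the RMT to the 100 %MSO cap", {
  log <- run_session(function(x) FALSE, session_config(seed = 12))
  expect_equal(log$final_rmt, 100)
  expect_true(log$capped)
  expect_gt(log$trials$estimate[30], 100)
})

test_that("sessions are bit-identical under the same seed", {
  vs <- virtual_subject(47)
  a <- run_session(vs, session_config(seed = 5))
  b <- run_session(vs, session_config(seed = 5))
  expect_identical(a$trials, b$trials)
  expect_identical(a$final_rmt, b$final_rmt)
})

test_that("rejected deliveries are retried without consuming the budget", {
  # every third delivery is rejected (NA), outcome is a step at 50
  maker <- function() {
    count <- 0L
    function(x) {
      count <<- count + 1L
      if (count %% 3L == 0L) NA else x >= 50
    }
  }
  log <- run_session(maker(), session_config(seed = 13))
  expect_equal(nrow(log$trials), 30)
  expect_false(log$truncated)
  expect_gt(sum(log$trials$rejected_repeats), 0)

  # a subject that always rejects hits the retry cap -> truncated log
  stuck <- run_session(function(x) NA,
                       session_config(seed = 14, max_retries = 3))
  expect_true(stuck$truncated)
  expect_equal(nrow(stuck$trials), 0)
})

test_that("trace-mode sessions route outcomes through EMG classification", {
  vs <- virtual_subject(50, reject_prob = 0.1)
  log <- run_session(vs, session_config(seed = 15, use_traces = TRUE))
  expect_equal(nrow(log$trials), 30)
  expect_true("mep_mv" %in% names(log$trials))
  expect_true(all(log$trials$mep_mv > 0))
})

test_that("final RMT rounds, caps and flags", {
  expect_equal(final_rmt(make_fake_log(c(50, 54.8))),
               list(rmt = 55, capped = FALSE))
  log_over <- make_fake_log(c(90, 113.2), intensity = c(90, 100))
  expect_equal(final_rmt(log_over), list(rmt = 100, capped = TRUE))
  expect_equal(final_rmt(make_fake_log(c(99, 100.0), intensity = c(99, 100))),
               list(rmt = 100, capped = FALSE))
  expect_error(final_rmt(make_fake_log(numeric(0))), "no estimates")
})

test_that("session log CSV round-trips losslessly at 4 decimals", {
  vs <- virtual_subject(52)
  log <- run_session(vs, session_config(seed = 16, target_amplitude = 0.2))
  path <- withr::local_tempfile(fileext = ".csv")
  write_session_log(log, path)
  back <- read_session_log(path)
  expect_equal(back$trials$intensity, log$trials$intensity)
  expect_identical(back$trials$outcome, log$trials$outcome)
  expect_equal(back$trials$estimate, log$trials$estimate,
               tolerance = 1e-4)
  expect_equal(back$trials$mep_mv, log$trials$mep_mv, tolerance = 1e-4)
  expect_equal(back$config$target_amplitude, 0.2)
  expect_equal(back$config$seed, 16L)
  expect_equal(back$final_rmt, log$final_rmt)
  expect_error(read_session_log(withr::local_tempfile(lines = "a,b\n1,2",
                                                      fileext = ".csv")),
               "lacks column")
})
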