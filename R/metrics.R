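#' Per-trial precision flags
#'
#' The precision criterion asks whether the running estimates of the
#' last three trials agree to within 2 \%MSO: the flag at trial `k`
#' (defined for `k >= 3`) is `TRUE` iff
#' `max(e[k-2:k]) - min(e[k-2:k]) <= tol`, boundary inclusive. The
#' first two positions are `NA`.
#'
#' @param estimates running threshold estimates (\%MSO), one per trial.
#' @param tol maximum allowed span of the three estimates (\%MSO).
#' @return logical vector, same length as `estimates`.
#' @examples
#' precision_flags(c(60, 57, 55, 54, 53))  # NA NA FALSE FALSE TRUE
#' @export
precision_flags <- function(estimates, tol = 2) {
  n <- length(estimates)
  flags <- rep(NA, n)
  if (n >= 3) {
    for (k in 3:n) {
      w <- estimates[(k - 2):k]
      flags[k] <- (max(w) - min(w)) <= tol
    }
  }
  flags
}

#' Session reference value
#'
#' The pragmatic reference threshold of a session: the arithmetic mean
#' of the tested intensities over trials 25–30 (six trials, both
#' endpoints included). An alternative reading based on the running ML
#' estimates is available via `source = "estimate"`.
#'
#' @param log an `rmt_session` (or any list with a `trials` data frame).
#' @param trials trial indices to average (default `25:30`).
#' @param source `"intensity"` (tested intensities, default) or
#'   `"estimate"` (running ML estimates).
#' @return the reference value (\%MSO, real).
#' @export
reference_value <- function(log, trials = 25:30,
                            source = c("intensity", "estimate")) {
  source <- match.arg(source)
  tr <- log$trials
  if (max(trials) > nrow(tr)) {
    stop("session log has only ", nrow(tr), " trials; need trial ",
         max(trials), call. = FALSE)
  }
  mean(tr[[source]][trials])
}

#' Per-trial accuracy flags
#'
#' The accuracy criterion asks whether the running estimate lies within
#' a tolerance band around the session's reference value. By default
#' the band is relative — ±5 \% of the reference (a 0.05 tolerance
#' level) — with an absolute ±`tol` \%MSO band available via
#' `relative = FALSE`. Boundaries are inclusive.
#'
#' @param estimates running threshold estimates (\%MSO).
#' @param reference the session reference value (\%MSO, > 0).
#' @param tol band half-width: a fraction of `reference` when
#'   `relative = TRUE` (default 0.05), otherwise \%MSO.
#' @param relative use the relative band?
#' @return logical vector, same length as `estimates`.
#' @examples
#' accuracy_flags(c(55, 58), reference = 54.6)  # TRUE FALSE
#' @export
accuracy_flags <- function(estimates, reference, tol = 0.05,
                           relative = TRUE) {
  stopifnot(is.numeric(reference), length(reference) == 1L,
            reference > 0)
  band <- if (relative) tol * reference else tol
  abs(estimates - reference) <= band
}

#' Convergence trial of a flag series
#'
#' Convergence is the first trial of the final run of consecutive
#' satisfied flags that extends to the end of the session. If the last
#' flag is not satisfied, the session did not converge (`NA`). `NA`
#' flags (e.g. the first two precision positions) count as unsatisfied.
#'
#' @param flags logical vector of per-trial criterion flags.
#' @return integer trial index, or `NA_integer_`.
#' @examples
#' convergence_trial(c(FALSE, FALSE, FALSE, TRUE, FALSE, TRUE, TRUE))  # 6
#' @export
convergence_trial <- function(flags) {
  stopifnot(length(flags) >= 1L)
  ok <- !is.na(flags) & flags
  n <- length(ok)
  if (!ok[n]) return(NA_integer_)
  bad <- which(!ok)
  if (length(bad) == 0L) {
    first_defined <- which(!is.na(flags))[1]
    return(as.integer(first_defined))
  }
  as.integer(max(bad) + 1L)
}

#' Trial at which 95 % of sessions have converged
#'
#' Given the convergence trials of a collection of sessions, computes
#' the per-trial proportion of sessions converged by trial `k`
#' (non-decreasing in `k`; non-converged sessions never count) and the
#' smallest `k` at which it reaches the criterion level.
#'
#' @param conv_trials integer vector of [convergence_trial()] results
#'   (NA = session never converged).
#' @param n_trials number of trials per session (default 30).
#' @param level required proportion of sessions (default 0.95).
#' @return list with `trial` (smallest qualifying trial, `NA` if the
#'   level is never reached) and `curve` (proportion per trial).
#' @export
criterion_trial_at_95 <- function(conv_trials, n_trials = 30,
                                  level = 0.95) {
  stopifnot(length(conv_trials) >= 1L)
  curve <- vapply(seq_len(n_trials), function(k) {
    mean(!is.na(conv_trials) & conv_trials <= k)
  }, numeric(1))
  hit <- which(curve >= level)
  list(trial = if (length(hit)) hit[1] else NA_integer_, curve = curve)
}

#' Intraclass correlation ICC(2,1)
#'
#' Two-way random-effects, absolute-agreement, single-measurement ICC
#' from an `n x k` matrix of measurements (subjects in rows, sessions in
#' columns; here `k = 2`):
#' \deqn{ICC(2,1) = \frac{MS_R - MS_E}{MS_R + (k-1) MS_E + \frac{k}{n}(MS_C - MS_E)}}
#' with the row, column and error mean squares of the two-way ANOVA
#' decomposition.
#'
#' @param x numeric matrix or data frame, subjects x sessions, no
#'   missing cells; or the first session's vector if `y` is given.
#' @param y optional second session's vector (paired with `x`).
#' @return the ICC value; `NA` with a warning when the total variance
#'   is zero (ICC undefined) or fewer than 3 subjects are available.
#' @examples
#' icc_2_1(cbind(c(1, 3, 5), c(2, 4, 6)))  # 8/9
#' @export
icc_2_1 <- function(x, y = NULL) {
  m <- if (is.null(y)) as.matrix(x) else cbind(x, y)
  storage.mode(m) <- "double"
  if (anyNA(m)) stop("missing cells are not allowed", call. = FALSE)
  n <- nrow(m); k <- ncol(m)
  if (n < 3) {
    warning("ICC undefined with fewer than 3 subjects", call. = FALSE)
    return(NA_real_)
  }
  grand <- mean(m)
  ssr <- k * sum((rowMeans(m) - grand)^2)
  ssc <- n * sum((colMeans(m) - grand)^2)
  sst <- sum((m - grand)^2)
  sse <- sst - ssr - ssc
  if (sst < .Machine$double.eps * n * k) {
    warning("zero total variance: ICC undefined", call. = FALSE)
    return(NA_real_)
  }
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
}

#' Within-subject standard deviation of paired sessions
#'
#' `Sw = sqrt(sum(d_i^2) / (2 n))` with `d_i` the per-subject
#' difference between the two sessions.
#'
#' @param session1,session2 paired measurement vectors.
#' @return Sw (\%MSO).
#' @export
within_subject_sd <- function(session1, session2) {
  if (length(session1) != length(session2)) {
    stop("sessions must have the same length", call. = FALSE)
  }
  d <- session1 - session2
  sqrt(sum(d^2) / (2 * length(d)))
}

#' Reproducibility coefficient
#'
#' `RC = 1.96 * sqrt(2) * Sw`: the 95 \% bound on the difference
#' between two measurements of the same subject.
#'
#' @param sw within-subject SD ([within_subject_sd()]).
#' @return RC (\%MSO).
#' @export
reproducibility_coefficient <- function(sw) {
  stopifnot(is.numeric(sw), all(sw >= 0))
  1.96 * sqrt(2) * sw
}

#' Standard error of measurement
#'
#' `SEM = SD * sqrt(1 - ICC)` with `SD` the between-subject standard
#' deviation: the expected error of a single threshold determination.
#'
#' @param between_subject_sd between-subject SD (\%MSO).
#' @param icc intraclass correlation in `[0, 1]`.
#' @return SEM (\%MSO).
#' @export
standard_error_of_measurement <- function(between_subject_sd, icc) {
  stopifnot(is.numeric(between_subject_sd), all(between_subject_sd >= 0))
  if (any(is.na(icc))) return(NA_real_)
  if (any(icc > 1)) stop("ICC cannot exceed 1", call. = FALSE)
  between_subject_sd * sqrt(1 - icc)
}

#' Bland–Altman agreement summary
#'
#' Mean and sample SD (n−1 denominator) of the per-subject differences
#' `session1 - session2`, with limits of agreement
#' `mean ± 1.96 * SD`.
#'
#' @param session1,session2 paired measurement vectors (n ≥ 2).
#' @return list with `mean_diff`, `sd_diff`, `loa_lower`, `loa_upper`,
#'   and `n`.
#' @export
bland_altman <- function(session1, session2) {
  if (length(session1) != length(session2)) {
    stop("sessions must have the same length", call. = FALSE)
  }
  if (length(session1) < 2) {
    stop("Bland-Altman needs at least 2 pairs", call. = FALSE)
  }
  d <- session1 - session2
  m <- mean(d); s <- stats::sd(d)
  loa <- bland_altman_limits(m, s)
  list(mean_diff = m, sd_diff = s,
       loa_lower = loa[1], loa_upper = loa[2], n = length(d))
}

#' Limits of agreement from a mean/SD summary
#'
#' `mean ± 1.96 * SD`, the form in which agreement analyses are
#' usually tabulated.
#'
#' @param mean_diff mean of the paired differences.
#' @param sd_diff SD of the paired differences.
#' @return numeric length-2 vector `c(lower, upper)`.
#' @examples
#' bland_altman_limits(-1.66, 8.99)  # c(-19.28, 15.96)
#' @export
bland_altman_limits <- function(mean_diff, sd_diff) {
  stopifnot(sd_diff >= 0)
  c(mean_diff - 1.96 * sd_diff, mean_diff + 1.96 * sd_diff)
}

#' Per-trial test-retest reliability of paired session collections
#'
#' For each trial index, takes the running estimate at that trial from
#' every subject's pair of sessions and computes ICC(2,1), the
#' within-subject SD, RC, SEM, Pearson's r, and the Bland–Altman
#' summary. The between-subject SD feeding the SEM is taken from the
#' per-subject means pooled across the two sessions. Also reports the
#' first trial at which ICC strictly exceeds the convergence level
#' (default 0.80).
#'
#' @param logs1,logs2 lists of `rmt_session` logs, paired by position
#'   (subject i's two sessions).
#' @param trials trial indices to evaluate (default `1:30`).
#' @param use `"estimate"` for the real-valued running estimates
#'   (default) or `"rounded"` for the device-grid rounded series.
#' @param icc_level ICC convergence level (strict, default 0.80).
#' @return a data frame of class `"reliability_report"` with one row
#'   per trial index and columns `trial, n, icc, sw, rc, sem, r,
#'   mean_diff, sd_diff, loa_lower, loa_upper`; the ICC convergence
#'   trial is attached as attribute `"icc_convergence"`.
#' @export
per_trial_reliability <- function(logs1, logs2, trials = 1:30,
                                  use = c("estimate", "rounded"),
                                  icc_level = 0.80) {
  use <- match.arg(use)
  if (length(logs1) != length(logs2)) {
    stop("paired collections must have the same length", call. = FALSE)
  }
  n <- length(logs1)
  pull <- function(log, k) {
    e <- log$trials$estimate
    if (k > length(e)) stop("log shorter than trial ", k, call. = FALSE)
    v <- e[k]
    if (use == "rounded") v <- next_intensity(v, log$config)
    v
  }
  rows <- lapply(trials, function(k) {
    a <- vapply(logs1, pull, numeric(1), k = k)
    b <- vapply(logs2, pull, numeric(1), k = k)
    icc <- if (n >= 3) suppressWarnings(icc_2_1(a, b)) else NA_real_
    sw <- within_subject_sd(a, b)
    bsd <- stats::sd(rowMeans(cbind(a, b)))
    ba <- if (n >= 2) bland_altman(a, b) else
      list(mean_diff = NA_real_, sd_diff = NA_real_,
           loa_lower = NA_real_, loa_upper = NA_real_)
    r <- if (n >= 3 && stats::sd(a) > 0 && stats::sd(b) > 0) {
      stats::cor(a, b)
    } else {
      NA_real_
    }
    data.frame(trial = k, n = n, icc = icc, sw = sw,
               rc = reproducibility_coefficient(sw),
               sem = if (is.na(icc)) NA_real_ else
                 standard_error_of_measurement(bsd, min(icc, 1)),
               r = r,
               mean_diff = ba$mean_diff, sd_diff = ba$sd_diff,
               loa_lower = ba$loa_lower, loa_upper = ba$loa_upper)
  })
  rep_df <- do.call(rbind, rows)
  class(rep_df) <- c("reliability_report", "data.frame")
  conv <- which(!is.na(rep_df$icc) & rep_df$icc > icc_level)
  attr(rep_df, "icc_convergence") <-
    if (length(conv)) rep_df$trial[conv[1]] else NA_integer_
  rep_df
}

#' @export
print.reliability_report <- function(x, digits = 3, ...) {
  cat("Per-trial test-retest reliability (", nrow(x), " trial indices, n = ",
      x$n[1], " pairs)\n", sep = "")
  conv <- attr(x, "icc_convergence")
  cat("  first trial with ICC > 0.80:",
      if (is.na(conv)) "not reached" else conv, "\n")
  last <- x[nrow(x), ]
  cat(sprintf("  at trial %d: ICC %.3f, Sw %.2f, RC %.2f, SEM %.2f\n",
              last$trial, last$icc, last$sw, last$rc, last$sem))
  cat(sprintf("  Bland-Altman: %.2f +/- %.2f, LoA [%.2f, %.2f]\n",
              last$mean_diff, last$sd_diff, last$loa_lower,
              last$loa_upper))
  invisible(x)
}

#' Plot per-trial ICC curves
#'
#' @param x a `reliability_report`.
#' @param level reference line (default 0.80).
#' @param ... passed to [graphics::plot()].
#' @export
plot.reliability_report <- function(x, level = 0.80, ...) {
  graphics::plot(x$trial, x$icc, type = "l", ylim = c(0, 1),
                 xlab = "trial", ylab = "ICC(2,1)", ...)
  graphics::abline(h = level, lty = 2, col = "red")
  invisible(x)
}
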