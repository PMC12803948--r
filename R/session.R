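#' Configuration of a threshold-hunting session
#'
#' Bundles the knobs of one adaptive PEST-MLE session: the MEP target
#' amplitude, the 30-trial budget, the random initialisation range
#' (20–60 \%MSO), the stimulator's intensity resolution and maximum
#' output, and the psychometric model settings used for the running ML
#' fit.
#'
#' @param target_amplitude MEP success cutoff in mV (0.05 or 0.2 in the
#'   standard protocol).
#' @param n_trials number of valid trials per session (default 30).
#' @param init_low,init_high bounds (\%MSO, inclusive) of the uniform
#'   random first intensity.
#' @param intensity_resolution stimulator step size (\%MSO, default 1).
#' @param device_max maximum stimulator output (\%MSO, default 100).
#' @param spread,spread_mode,anchors,anchor_weight,epsilon psychometric
#'   model settings, see [pest_mle()].
#' @param estimate_lower,estimate_upper threshold search interval for
#'   the ML fit; the upper bound deliberately exceeds `device_max` so
#'   "threshold above device maximum" is representable before capping.
#' @param max_retries cap on consecutive rejected deliveries at one
#'   trial before the session is abandoned as truncated.
#' @param seed optional integer seed; when given, `run_session` seeds
#'   the R RNG with it so the session is exactly reproducible.
#' @param use_traces if `TRUE` and the subject is a [virtual_subject()],
#'   outcomes are derived from synthesized EMG traces through
#'   [classify_trial()] rather than by direct amplitude thresholding.
#' @return a list of class `"session_config"`.
#' @export
session_config <- function(target_amplitude = 0.05, n_trials = 30,
                           init_low = 20, init_high = 60,
                           intensity_resolution = 1, device_max = 100,
                           spread = 3.5,
                           spread_mode = c("absolute", "relative"),
                           anchors = TRUE, anchor_weight = 1,
                           epsilon = 1e-12,
                           estimate_lower = 1, estimate_upper = 150,
                           max_retries = 10, seed = NULL,
                           use_traces = FALSE) {
  spread_mode <- match.arg(spread_mode)
  stopifnot(target_amplitude > 0, n_trials >= 1,
            init_low < init_high, init_high <= device_max,
            intensity_resolution > 0, device_max > 0,
            max_retries >= 1)
  structure(list(target_amplitude = target_amplitude,
                 n_trials = as.integer(n_trials),
                 init_low = as.integer(init_low),
                 init_high = as.integer(init_high),
                 intensity_resolution = intensity_resolution,
                 device_max = device_max,
                 spread = spread, spread_mode = spread_mode,
                 anchors = anchors, anchor_weight = anchor_weight,
                 epsilon = epsilon,
                 estimate_lower = estimate_lower,
                 estimate_upper = estimate_upper,
                 max_retries = as.integer(max_retries),
                 seed = seed,
                 use_traces = use_traces),
            class = "session_config")
}

#' Random initial intensity
#'
#' Uniform integer draw from `{init_low, ..., init_high}` (default
#' 20–60 \%MSO), from the R global RNG stream.
#'
#' @param config a [session_config()].
#' @return integer \%MSO.
#' @export
initial_intensity <- function(config = session_config()) {
  config$init_low + sample.int(config$init_high - config$init_low + 1L, 1L) - 1L
}

#' Next tested intensity from a threshold estimate
#'
#' The tested intensity tracks the running ML estimate: the estimate is
#' rounded half-away-from-zero to the stimulator resolution and clamped
#' to `[1, device_max]`. Estimates above the device maximum therefore
#' map to 100 \%MSO.
#'
#' @param estimate running ML threshold estimate (\%MSO, real).
#' @param config a [session_config()].
#' @return intensity on the stimulator grid (\%MSO).
#' @examples
#' next_intensity(55.4)   # 55
#' next_intensity(102.3)  # 100
#' @export
next_intensity <- function(estimate, config = session_config()) {
  stopifnot(is.finite(estimate))
  r <- config$intensity_resolution
  v <- sign(estimate) * floor(abs(estimate) / r + 0.5) * r
  min(max(v, 1), config$device_max)
}

# one fit of the running estimate over the valid trials so far
.running_fit <- function(intensity, outcome, config) {
  pest_mle(intensity, outcome,
           spread = config$spread, spread_mode = config$spread_mode,
           anchors = config$anchors, anchor_weight = config$anchor_weight,
           lower = config$estimate_lower, upper = config$estimate_upper,
           epsilon = config$epsilon)$threshold
}

#' Replay the running estimate series for a fixed trial sequence
#'
#' Recomputes the ML estimate after each trial of a recorded session
#' (the estimate after trial `k` uses trials `1..k` plus the anchors).
#' Useful for replaying logged sessions or driving the estimator with
#' manually entered outcomes.
#'
#' @param intensity,outcome trial sequence.
#' @param config a [session_config()].
#' @return numeric vector of running estimates, one per trial.
#' @export
running_estimates <- function(intensity, outcome,
                              config = session_config()) {
  stopifnot(length(intensity) == length(outcome))
  vapply(seq_along(intensity), function(k) {
    .running_fit(intensity[seq_len(k)], outcome[seq_len(k)], config)
  }, numeric(1))
}

#' Run one adaptive threshold-hunting session
#'
#' Executes the sequential PEST-MLE loop: an initial intensity is drawn
#' uniformly from 20–60 \%MSO; after every valid trial the threshold is
#' re-estimated by maximum likelihood over all trials so far (with the
#' virtual anchors), and the next tested intensity is the rounded
#' estimate. Rejected deliveries (pre-stimulus voluntary EMG) are
#' repeated at the same intensity without consuming the trial budget,
#' up to `max_retries` consecutive repeats.
#'
#' @param subject either a [virtual_subject()] (outcomes sampled from
#'   its generative model, via amplitude thresholding or synthesized
#'   traces per `config$use_traces`) or a function `f(x)` returning
#'   `TRUE` (success), `FALSE` (failure) or `NA` (rejected delivery).
#' @param config a [session_config()].
#' @param threshold optional session-realised threshold passed to the
#'   virtual subject (see [realize_session_threshold()]).
#' @return an object of class `"rmt_session"`: list with `trials` (data
#'   frame: `trial`, `intensity`, `outcome`, `rejected_repeats`,
#'   `estimate`, and `mep_mv` when amplitudes were sampled), `final_rmt`
#'   (capped integer \%MSO), `capped`, `truncated`, `config`, `seed`.
#' @examples
#' step_subject <- function(x) x >= 50
#' log <- run_session(step_subject, session_config(seed = 1))
#' log$final_rmt
#' @export
run_session <- function(subject, config = session_config(),
                        threshold = NULL) {
  if (!is.null(config$seed)) set.seed(config$seed)
  is_vs <- inherits(subject, "virtual_subject")
  if (!is_vs && !is.function(subject)) {
    stop("'subject' must be a virtual_subject or a function",
         call. = FALSE)
  }

  ask <- function(x) {
    # returns list(outcome = TRUE/FALSE/NA, amp = numeric or NA)
    if (!is_vs) {
      return(list(outcome = subject(x), amp = NA_real_))
    }
    if (config$use_traces) {
      inj <- stats::runif(1) < subject$reject_prob
      tr <- sample_trace(subject, x, threshold = threshold,
                         inject_artifact = inj)
      cls <- classify_trial(tr, config$target_amplitude)
      list(outcome = switch(cls, success = TRUE, failure = FALSE,
                            rejected = NA),
           amp = attr(tr, "mep_amplitude"))
    } else {
      if (subject$reject_prob > 0 &&
          stats::runif(1) < subject$reject_prob) {
        return(list(outcome = NA, amp = NA_real_))
      }
      amp <- sample_mep_amplitude(subject, x, threshold = threshold)
      list(outcome = amp > config$target_amplitude, amp = amp)
    }
  }

  n <- config$n_trials
  intensity <- numeric(0); outcome <- logical(0)
  repeats <- integer(0); estimates <- numeric(0); amps <- numeric(0)
  truncated <- FALSE
  x <- initial_intensity(config)

  for (k in seq_len(n)) {
    rej <- 0L
    res <- NULL
    repeat {
      res <- tryCatch(ask(x), error = function(e) NULL)
      if (is.null(res)) { truncated <- TRUE; break }
      if (!is.na(res$outcome)) break
      rej <- rej + 1L
      if (rej > config$max_retries) { truncated <- TRUE; break }
    }
    if (truncated) break
    intensity <- c(intensity, x)
    outcome <- c(outcome, res$outcome)
    repeats <- c(repeats, rej)
    amps <- c(amps, res$amp)
    est <- .running_fit(intensity, outcome, config)
    estimates <- c(estimates, est)
    x <- next_intensity(est, config)
  }

  trials <- data.frame(trial = seq_along(intensity),
                       intensity = intensity, outcome = outcome,
                       rejected_repeats = repeats,
                       estimate = estimates)
  if (any(!is.na(amps))) trials$mep_mv <- amps

  log <- structure(list(trials = trials, config = config,
                        seed = config$seed, truncated = truncated),
                   class = "rmt_session")
  if (nrow(trials) > 0) {
    fr <- final_rmt(log)
    log$final_rmt <- fr$rmt
    log$capped <- fr$capped
  } else {
    log$final_rmt <- NA_real_
    log$capped <- NA
  }
  log
}

#' Final RMT of a session
#'
#' The last running ML estimate, rounded to the stimulator resolution
#' and capped at the device maximum (100 \%MSO). Sessions whose
#' estimate exceeded the device maximum are reported as 100 \%MSO with
#' `capped = TRUE`.
#'
#' @param log an [run_session()] log (or any list with a `trials` data
#'   frame holding an `estimate` column).
#' @return list with `rmt` (\%MSO on the device grid) and `capped`.
#' @export
final_rmt <- function(log) {
  est <- log$trials$estimate
  if (is.null(est) || length(est) == 0) {
    stop("session log has no estimates", call. = FALSE)
  }
  cfg <- if (!is.null(log$config)) log$config else session_config()
  last <- est[length(est)]
  r <- cfg$intensity_resolution
  v <- sign(last) * floor(abs(last) / r + 0.5) * r
  list(rmt = min(v, cfg$device_max), capped = v > cfg$device_max)
}

#' @export
print.rmt_session <- function(x, ...) {
  cat(sprintf("PEST-MLE session: %d valid trials, target %g mV\n",
              nrow(x$trials), x$config$target_amplitude))
  if (x$truncated) cat("  TRUNCATED before completing the budget\n")
  if (nrow(x$trials) > 0) {
    cat(sprintf("  final RMT: %g %%MSO%s (last estimate %.2f)\n",
                x$final_rmt, if (isTRUE(x$capped)) " [capped]" else "",
                x$trials$estimate[nrow(x$trials)]))
    cat(sprintf("  successes: %d / %d\n", sum(x$trials$outcome),
                nrow(x$trials)))
  }
  invisible(x)
}

#' Plot one hunting session
#'
#' Tested intensity and running estimate per trial, with success and
#' failure marks, in the style of a single-session convergence figure.
#'
#' @param x an `rmt_session`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.rmt_session <- function(x, ...) {
  tr <- x$trials
  if (nrow(tr) == 0) stop("empty session log", call. = FALSE)
  ylim <- range(tr$intensity, tr$estimate)
  graphics::plot(tr$trial, tr$intensity, type = "b", pch = 16,
                 col = "steelblue", xlab = "trial",
                 ylab = "intensity (%MSO)", ylim = ylim, ...)
  graphics::lines(tr$trial, tr$estimate, lty = 2, col = "grey40")
  graphics::points(tr$trial[tr$outcome], tr$intensity[tr$outcome],
                   pch = 1, cex = 1.8, col = "forestgreen")
  graphics::legend("topright", bty = "n",
                   legend = c("tested intensity", "running estimate",
                              "success"),
                   col = c("steelblue", "grey40", "forestgreen"),
                   lty = c(1, 2, NA), pch = c(16, NA, 1))
  invisible(x)
}

#' Read / write a session log as CSV
#'
#' Plain-text dialect: leading `#` comment lines carry the config
#' snapshot and seed as `# key: value` pairs, followed by the columns
#' `trial, intensity_pct_mso, outcome, rejected_repeats,
#' estimate_pct_mso` (plus `mep_mv` when amplitudes were recorded).
#' Estimates are written at 4 decimal places and round-trip losslessly
#' at that precision.
#'
#' @param log an `rmt_session`.
#' @param path file path.
#' @return `write_session_log` returns `path` invisibly;
#'   `read_session_log` returns an `rmt_session`.
#' @export
write_session_log <- function(log, path) {
  stopifnot(inherits(log, "rmt_session"))
  cfg <- log$config
  hdr <- c(
    sprintf("# target_amplitude: %g", cfg$target_amplitude),
    sprintf("# n_trials: %d", cfg$n_trials),
    sprintf("# init_low: %d", cfg$init_low),
    sprintf("# init_high: %d", cfg$init_high),
    sprintf("# intensity_resolution: %g", cfg$intensity_resolution),
    sprintf("# device_max: %g", cfg$device_max),
    sprintf("# spread: %g", cfg$spread),
    sprintf("# spread_mode: %s", cfg$spread_mode),
    sprintf("# anchors: %s", cfg$anchors),
    sprintf("# seed: %s", if (is.null(log$seed)) "NA" else log$seed),
    sprintf("# truncated: %s", log$truncated)
  )
  tr <- log$trials
  has_amp <- !is.null(tr$mep_mv)
  cols <- c("trial", "intensity_pct_mso", "outcome", "rejected_repeats",
            "estimate_pct_mso", if (has_amp) "mep_mv")
  body <- c(paste(cols, collapse = ","),
            vapply(seq_len(nrow(tr)), function(i) {
              paste(c(tr$trial[i],
                      sprintf("%g", tr$intensity[i]),
                      as.integer(tr$outcome[i]),
                      tr$rejected_repeats[i],
                      sprintf("%.4f", tr$estimate[i]),
                      if (has_amp) sprintf("%.4f", tr$mep_mv[i])),
                    collapse = ",")
            }, character(1)))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' @rdname write_session_log
#' @export
read_session_log <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  get <- function(key, default = NULL) {
    m <- grep(paste0("^#\\s*", key, "\\s*:"), hdr, value = TRUE)
    if (length(m) != 1L) return(default)
    trimws(sub(".*?:\\s*", "", m))
  }
  num <- function(key, default) {
    v <- get(key); if (is.null(v)) default else as.numeric(v)
  }
  seed <- get("seed", "NA")
  cfg <- session_config(
    target_amplitude = num("target_amplitude", 0.05),
    n_trials = num("n_trials", 30),
    init_low = num("init_low", 20),
    init_high = num("init_high", 60),
    intensity_resolution = num("intensity_resolution", 1),
    device_max = num("device_max", 100),
    spread = num("spread", 3.5),
    spread_mode = get("spread_mode", "absolute"),
    anchors = identical(get("anchors", "TRUE"), "TRUE"),
    seed = if (identical(seed, "NA")) NULL else as.integer(seed)
  )
  body <- lines[!grepl("^#", lines)]
  df <- utils::read.csv(text = body)
  required <- c("trial", "intensity_pct_mso", "outcome",
                "rejected_repeats", "estimate_pct_mso")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("session log ", path, " lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  trials <- data.frame(trial = df$trial,
                       intensity = df$intensity_pct_mso,
                       outcome = df$outcome == 1,
                       rejected_repeats = df$rejected_repeats,
                       estimate = df$estimate_pct_mso)
  if (!is.null(df$mep_mv)) trials$mep_mv <- df$mep_mv
  log <- structure(list(trials = trials, config = cfg, seed = cfg$seed,
                        truncated = identical(get("truncated", "FALSE"),
                                              "TRUE")),
                   class = "rmt_session")
  if (nrow(trials) > 0) {
    fr <- final_rmt(log)
    log$final_rmt <- fr$rmt
    log$capped <- fr$capped
  }
  log
}
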