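#' Configuration of a simulated test-retest study
#'
#' Describes a simulated replication of the standard design: a cohort
#' of virtual subjects, each measured in four sessions (two per day on
#' two days), with both MEP target amplitudes hunted in each session
#' (0.05 mV first, then 0.2 mV). Comparing sessions 1 vs 2 gives
#' within-day reliability; sessions 1 vs 3 give between-day
#' reliability.
#'
#' The subject's true threshold is drawn for the 0.05 mV target; the
#' threshold for any other target amplitude `A` follows from the
#' lognormal amplitude model as
#' `t(A) = t + gen_spread * log(A / 0.05) / amp_sigma_log`, so the two
#' targets are generated by one consistent amplitude process and are
#' correlated within subject.
#'
#' @param n_subjects cohort size (default 50).
#' @param targets MEP target amplitudes in mV, hunted in order.
#' @param threshold_range bounds of the uniform distribution of true
#'   0.05 mV-target thresholds (\%MSO).
#' @param gen_spread,amp_sigma_log,day_sd,session_sd,reject_prob
#'   generative subject parameters, see [virtual_subject()].
#' @param n_trials trials per session (default 30).
#' @param seed master seed; fully determines the study.
#' @param engine additional [session_config()] overrides applied to
#'   every session (a named list, e.g. `list(spread = 3)`).
#' @return a list of class `"study_config"`.
#' @export
study_config <- function(n_subjects = 50, targets = c(0.05, 0.2),
                         threshold_range = c(35, 65), gen_spread = 3.5,
                         amp_sigma_log = 0.9, day_sd = 3,
                         session_sd = 1, reject_prob = 0,
                         n_trials = 30, seed = NULL, engine = list()) {
  stopifnot(n_subjects >= 1, length(targets) >= 1, all(targets > 0),
            length(threshold_range) == 2L,
            threshold_range[1] < threshold_range[2],
            gen_spread > 0, day_sd >= 0, session_sd >= 0,
            n_trials >= 1)
  structure(list(n_subjects = as.integer(n_subjects), targets = targets,
                 threshold_range = threshold_range,
                 gen_spread = gen_spread, amp_sigma_log = amp_sigma_log,
                 day_sd = day_sd, session_sd = session_sd,
                 reject_prob = reject_prob,
                 n_trials = as.integer(n_trials), seed = seed,
                 engine = engine),
            class = "study_config")
}

.session_key <- function(subject, session, target) {
  sprintf("sub%03d_ses%d_t%s", subject, session,
          gsub("\\.", "p", format(target)))
}

#' Simulate a full test-retest study
#'
#' Draws the cohort, realises the per-day and per-session threshold
#' drift for every subject, and runs one adaptive hunting session per
#' (subject, session 1–4, target amplitude) cell. Deterministic under
#' the master seed; each session log additionally records its own
#' derived seed so it can be replayed in isolation.
#'
#' @param config a [study_config()].
#' @return an object of class `"rmt_study"`: list with `logs` (list of
#'   `rmt_session`), `index` (data frame: `subject`, `day`, `session`,
#'   `target`, `key`, `true_threshold`, `session_threshold`),
#'   `subjects` (true 0.05 mV-target thresholds), and `config`.
#' @examples
#' study <- simulate_study(study_config(n_subjects = 2, seed = 1))
#' nrow(study$index)  # 2 subjects x 4 sessions x 2 targets = 16
#' @export
simulate_study <- function(config = study_config()) {
  stopifnot(inherits(config, "study_config"))
  if (!is.null(config$seed)) set.seed(config$seed)

  base_cfg <- function(target, seed) {
    args <- c(list(target_amplitude = target, n_trials = config$n_trials,
                   seed = seed),
              config$engine)
    do.call(session_config, args[!duplicated(names(args))])
  }

  logs <- list()
  idx <- list()
  thresholds <- numeric(config$n_subjects)
  for (s in seq_len(config$n_subjects)) {
    t05 <- stats::runif(1, config$threshold_range[1],
                        config$threshold_range[2])
    thresholds[s] <- t05
    proto <- virtual_subject(t05, gen_spread = config$gen_spread,
                             amp_sigma_log = config$amp_sigma_log,
                             day_sd = config$day_sd,
                             session_sd = config$session_sd,
                             reject_prob = config$reject_prob)
    effects <- draw_session_effects(proto)
    for (ses in 1:4) {
      shift <- realize_session_threshold(proto, ses, effects) - t05
      for (target in config$targets) {
        t_target <- t05 +
          config$gen_spread * log(target / 0.05) / config$amp_sigma_log
        vs <- virtual_subject(t_target, gen_spread = config$gen_spread,
                              amp_sigma_log = config$amp_sigma_log,
                              day_sd = config$day_sd,
                              session_sd = config$session_sd,
                              target_amplitude = target,
                              reject_prob = config$reject_prob)
        seed_i <- sample.int(.Machine$integer.max - 1L, 1L)
        cfg <- base_cfg(target, seed_i)
        log <- run_session(vs, cfg, threshold = t_target + shift)
        key <- .session_key(s, ses, target)
        logs[[key]] <- log
        idx[[length(idx) + 1L]] <- data.frame(
          subject = s, day = if (ses <= 2) 1L else 2L, session = ses,
          target = target, key = key, true_threshold = t_target,
          session_threshold = t_target + shift)
      }
    }
  }
  structure(list(logs = logs, index = do.call(rbind, idx),
                 subjects = thresholds, config = config),
            class = "rmt_study")
}

#' @export
print.rmt_study <- function(x, ...) {
  cat(sprintf("Simulated RMT study: %d subjects x 4 sessions x %d targets = %d logs\n",
              x$config$n_subjects, length(x$config$targets),
              length(x$logs)))
  tr <- sum(vapply(x$logs, function(l) l$truncated, logical(1)))
  if (tr > 0) cat("  truncated sessions:", tr, "\n")
  invisible(x)
}

# estimate matrix helpers -------------------------------------------------

.study_logs <- function(study, target, session) {
  keys <- study$index$key[study$index$target == target &
                            study$index$session == session]
  study$logs[keys]
}

#' Analyze a simulated study
#'
#' Runs the full evaluation battery on a simulated (or re-read) study:
#'
#' * pooled precision and accuracy convergence curves over all sessions
#'   of each target, with the trial at which 95 \% of sessions satisfy
#'   each criterion;
#' * within-day (session 1 vs 2) and between-day (session 1 vs 3)
#'   per-trial reliability reports ([per_trial_reliability()]);
#' * late-trial (19–30) per-session success proportions and mean MEP
#'   amplitudes, summarising whether the final estimates behave like a
#'   conventional 50 \%-success threshold.
#'
#' Truncated sessions are excluded from the affected comparisons with a
#' warning.
#'
#' @param study an `rmt_study` from [simulate_study()] or
#'   [read_study()].
#' @param late_trials trial window for the late-phase summaries.
#' @return an object of class `"rmt_study_report"`: per-target lists
#'   with elements `precision`, `accuracy` (each a
#'   [criterion_trial_at_95()] result plus the per-session convergence
#'   trials), `within`, `between` (reliability reports), and `late`
#'   (data frame of per-session success proportion / mean amplitude).
#' @export
analyze_study <- function(study, late_trials = 19:30) {
  stopifnot(inherits(study, "rmt_study"))
  n_trials <- study$config$n_trials
  out <- list()
  for (target in study$config$targets) {
    tkey <- format(target)
    keys <- study$index$key[study$index$target == target]
    logs <- study$logs[keys]
    complete <- vapply(logs, function(l) {
      !l$truncated && nrow(l$trials) == n_trials
    }, logical(1))
    if (any(!complete)) {
      warning(sum(!complete), " incomplete session(s) excluded for target ",
              tkey, call. = FALSE)
    }
    logs <- logs[complete]

    prec_conv <- vapply(logs, function(l) {
      convergence_trial(precision_flags(l$trials$estimate))
    }, integer(1))
    acc_conv <- vapply(logs, function(l) {
      ref <- reference_value(l)
      convergence_trial(accuracy_flags(l$trials$estimate, ref))
    }, integer(1))
    precision <- criterion_trial_at_95(prec_conv, n_trials)
    precision$per_session <- prec_conv
    accuracy <- criterion_trial_at_95(acc_conv, n_trials)
    accuracy$per_session <- acc_conv

    pair_report <- function(ses_a, ses_b) {
      la <- .study_logs(study, target, ses_a)
      lb <- .study_logs(study, target, ses_b)
      ok <- vapply(la, function(l) !l$truncated, logical(1)) &
        vapply(lb, function(l) !l$truncated, logical(1))
      if (sum(ok) < 3) {
        warning("fewer than 3 complete pairs for sessions ", ses_a,
                " vs ", ses_b, call. = FALSE)
        return(NULL)
      }
      per_trial_reliability(la[ok], lb[ok], trials = seq_len(n_trials))
    }

    late <- do.call(rbind, lapply(names(logs), function(k) {
      tr <- logs[[k]]$trials
      data.frame(key = k,
                 success_rate = mean(tr$outcome[late_trials]),
                 mean_amplitude = if (!is.null(tr$mep_mv)) {
                   mean(tr$mep_mv[late_trials])
                 } else {
                   NA_real_
                 })
    }))

    out[[tkey]] <- list(target = target,
                        n_sessions = length(logs),
                        precision = precision, accuracy = accuracy,
                        within = pair_report(1, 2),
                        between = pair_report(1, 3),
                        late = late)
  }
  structure(list(targets = out, config = study$config),
            class = "rmt_study_report")
}

#' @export
print.rmt_study_report <- function(x, ...) {
  cat("RMT study report\n")
  for (tkey in names(x$targets)) {
    r <- x$targets[[tkey]]
    cat(sprintf("\n-- target %s mV (%d sessions) --\n", tkey,
                r$n_sessions))
    cat(sprintf("  95%% precision criterion trial: %s\n",
                ifelse(is.na(r$precision$trial), "not reached",
                       r$precision$trial)))
    cat(sprintf("  95%% accuracy  criterion trial: %s\n",
                ifelse(is.na(r$accuracy$trial), "not reached",
                       r$accuracy$trial)))
    for (cmp in c("within", "between")) {
      rep <- r[[cmp]]
      if (is.null(rep)) next
      last <- rep[nrow(rep), ]
      cat(sprintf(
        "  %s-day @ trial %d: ICC %.3f, RC %.2f, SEM %.2f, LoA [%.2f, %.2f]\n",
        cmp, last$trial, last$icc, last$rc, last$sem, last$loa_lower,
        last$loa_upper))
    }
    cat(sprintf("  late trials: mean success rate %.3f",
                mean(r$late$success_rate)))
    if (!all(is.na(r$late$mean_amplitude))) {
      cat(sprintf(", mean MEP amplitude %.3f mV",
                  mean(r$late$mean_amplitude)))
    }
    cat("\n")
  }
  invisible(x)
}

#' Write / read a study as a directory of session CSVs
#'
#' One session-log CSV per (subject, session, target) cell plus a
#' `manifest.json` recording the study configuration and the file
#' index, so every log stays independently replayable.
#'
#' @param study an `rmt_study`.
#' @param dir output directory (created if needed).
#' @return `write_study` returns `dir` invisibly; `read_study` returns
#'   an `rmt_study`.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "rmt_study"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (key in names(study$logs)) {
    write_session_log(study$logs[[key]],
                      file.path(dir, paste0(key, ".csv")))
  }
  manifest <- list(
    package = "pestmle",
    n_subjects = study$config$n_subjects,
    targets = study$config$targets,
    threshold_range = study$config$threshold_range,
    gen_spread = study$config$gen_spread,
    amp_sigma_log = study$config$amp_sigma_log,
    day_sd = study$config$day_sd,
    session_sd = study$config$session_sd,
    reject_prob = study$config$reject_prob,
    n_trials = study$config$n_trials,
    seed = study$config$seed,
    index = study$index[, c("subject", "day", "session", "target",
                            "key", "true_threshold",
                            "session_threshold")]
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @rdname write_study
#' @export
read_study <- function(dir) {
  mf <- file.path(dir, "manifest.json")
  if (!file.exists(mf)) {
    stop("no manifest.json in ", dir, ": not a study directory",
         call. = FALSE)
  }
  manifest <- jsonlite::read_json(mf, simplifyVector = TRUE)
  config <- study_config(
    n_subjects = manifest$n_subjects, targets = manifest$targets,
    threshold_range = manifest$threshold_range,
    gen_spread = manifest$gen_spread,
    amp_sigma_log = manifest$amp_sigma_log,
    day_sd = manifest$day_sd, session_sd = manifest$session_sd,
    reject_prob = manifest$reject_prob, n_trials = manifest$n_trials,
    seed = manifest$seed)
  index <- as.data.frame(manifest$index)
  logs <- lapply(index$key, function(key) {
    read_session_log(file.path(dir, paste0(key, ".csv")))
  })
  names(logs) <- index$key
  structure(list(logs = logs, index = index,
                 subjects = unique(index$true_threshold),
                 config = config),
            class = "rmt_study")
}
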