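#' Virtual TMS subject
#'
#' Generative model of a stimulated subject used to exercise the
#' threshold-hunting machinery without hardware. The subject has a true
#' cumulative-Gaussian intensity–response relation,
#' `P(MEP > target | x) = Phi((x - true_threshold) / gen_spread)`,
#' right-skewed (lognormal) single-trial MEP amplitudes tied to that
#' relation, and additive Gaussian day-to-day and session-to-session
#' threshold drift.
#'
#' The amplitude model is constructed so that thresholding the sampled
#' amplitude at `target_amplitude` reproduces the Bernoulli response
#' probability exactly: the lognormal median at intensity `x` is
#' `target_amplitude * exp(amp_sigma_log * z(x))` with
#' `z(x) = (x - true_threshold) / gen_spread`, and the lognormal shape
#' is `amp_sigma_log`. Then
#' `P(amplitude > target_amplitude | x) = Phi(z(x))` identically.
#'
#' @param true_threshold true threshold (\%MSO) for `target_amplitude`.
#' @param gen_spread steepness of the true response curve (\%MSO).
#' @param amp_sigma_log lognormal shape of the MEP amplitude
#'   distribution at fixed intensity (dimensionless).
#' @param day_sd SD of the between-day threshold drift (\%MSO).
#' @param session_sd SD of the within-day, between-session drift (\%MSO).
#' @param target_amplitude MEP cutoff (mV) that `true_threshold` refers
#'   to.
#' @param reject_prob probability that a delivery is rejected for
#'   pre-stimulus voluntary EMG (0 disables rejection).
#' @return an object of class `"virtual_subject"`.
#' @examples
#' vs <- virtual_subject(50)
#' set.seed(1); sample_outcome(vs, 50)
#' @export
virtual_subject <- function(true_threshold, gen_spread = 3.5,
                            amp_sigma_log = 0.9, day_sd = 3,
                            session_sd = 1, target_amplitude = 0.05,
                            reject_prob = 0) {
  stopifnot(is.numeric(true_threshold), true_threshold > 0,
            true_threshold <= 150, gen_spread > 0, amp_sigma_log > 0,
            day_sd >= 0, session_sd >= 0, target_amplitude > 0,
            reject_prob >= 0, reject_prob < 1)
  structure(list(true_threshold = true_threshold,
                 gen_spread = gen_spread,
                 amp_sigma_log = amp_sigma_log,
                 day_sd = day_sd, session_sd = session_sd,
                 target_amplitude = target_amplitude,
                 reject_prob = reject_prob),
            class = "virtual_subject")
}

#' @export
print.virtual_subject <- function(x, ...) {
  cat(sprintf(paste0("virtual subject: threshold %.1f %%MSO ",
                     "(spread %.2f) for target %g mV\n"),
              x$true_threshold, x$gen_spread, x$target_amplitude))
  cat(sprintf("  drift SDs: day %.2f, session %.2f %%MSO\n",
              x$day_sd, x$session_sd))
  invisible(x)
}

#' Sample a binary trial outcome
#'
#' Bernoulli draw with success probability
#' `Phi((x - threshold) / gen_spread)`. Uses the R global RNG stream.
#'
#' @param subject a [virtual_subject()].
#' @param x tested intensity (\%MSO).
#' @param threshold optional session-realised threshold overriding
#'   `subject$true_threshold` (see [realize_session_threshold()]).
#' @return logical.
#' @export
sample_outcome <- function(subject, x, threshold = NULL) {
  stopifnot(inherits(subject, "virtual_subject"))
  t0 <- if (is.null(threshold)) subject$true_threshold else threshold
  p <- stats::pnorm((x - t0) / subject$gen_spread)
  stats::runif(length(x)) < p
}

#' Sample single-trial MEP amplitudes
#'
#' Lognormal draws whose exceedance probability over the target
#' amplitude equals the subject's response probability at `x` exactly
#' (see [virtual_subject()]).
#'
#' @inheritParams sample_outcome
#' @param n number of draws.
#' @return numeric vector of amplitudes in mV (always positive).
#' @export
sample_mep_amplitude <- function(subject, x, n = 1, threshold = NULL) {
  stopifnot(inherits(subject, "virtual_subject"), length(x) == 1L)
  t0 <- if (is.null(threshold)) subject$true_threshold else threshold
  z <- (x - t0) / subject$gen_spread
  mu <- log(subject$target_amplitude) + subject$amp_sigma_log * z
  stats::rlnorm(n, meanlog = mu, sdlog = subject$amp_sigma_log)
}

#' Synthesize a stimulus-locked EMG trace
#'
#' Builds a 5 kHz sweep with a flat (optionally noisy) baseline, a
#' biphasic MEP waveform planted inside the 15–40 ms post-stimulus
#' window whose peak-to-peak amplitude is a [sample_mep_amplitude()]
#' draw, and, optionally, an injected pre-stimulus artifact burst so the
#' rejection path of [classify_trial()] can be exercised.
#'
#' @inheritParams sample_outcome
#' @param sampling_rate Hz.
#' @param pre_ms,post_ms trace extent around the stimulus (ms).
#' @param baseline_noise_sd SD of Gaussian baseline noise in mV (keep
#'   well below half the 0.05 mV rejection cutoff; 0 = clean).
#' @param inject_artifact if `TRUE`, add a 0.2 mV p2p burst around
#'   −30 ms so the trace is rejected.
#' @param amplitude optional fixed MEP peak-to-peak amplitude (mV)
#'   bypassing the random draw.
#' @return an [emg_trace()], with the drawn amplitude attached as
#'   attribute `"mep_amplitude"`.
#' @export
sample_trace <- function(subject, x, threshold = NULL,
                         sampling_rate = 5000, pre_ms = 70, post_ms = 50,
                         baseline_noise_sd = 0, inject_artifact = FALSE,
                         amplitude = NULL) {
  stopifnot(inherits(subject, "virtual_subject"), pre_ms >= 65,
            post_ms >= 40)
  step <- 1000 / sampling_rate
  n_pre <- round(pre_ms / step)
  n_post <- round(post_ms / step)
  n <- n_pre + 1L + n_post
  stim <- n_pre + 1L
  s <- if (baseline_noise_sd > 0) {
    stats::rnorm(n, 0, baseline_noise_sd)
  } else {
    numeric(n)
  }
  amp <- if (is.null(amplitude)) {
    sample_mep_amplitude(subject, x, threshold = threshold)
  } else {
    amplitude
  }
  # biphasic wave: one full sine cycle over 18-36 ms, scaled to exact p2p
  i0 <- stim + round(18 / step)
  i1 <- stim + round(36 / step)
  idx <- seq.int(i0, i1)
  wave <- sin(2 * pi * seq(0, 1, length.out = length(idx)))
  wave <- wave / (max(wave) - min(wave)) * amp
  s[idx] <- s[idx] + wave
  if (inject_artifact) {
    a0 <- stim + round(-32 / step)
    a1 <- stim + round(-28 / step)
    ai <- seq.int(a0, a1)
    burst <- sin(2 * pi * seq(0, 1, length.out = length(ai)))
    s[ai] <- s[ai] + burst / (max(burst) - min(burst)) * 0.2
  }
  tr <- emg_trace(s, sampling_rate = sampling_rate, stimulus_index = stim)
  attr(tr, "mep_amplitude") <- amp
  tr
}

#' Draw day and session drift effects
#'
#' One draw of the random effects for the standard two-day, four-session
#' design: two day effects (`~ Normal(0, day_sd)`) and four session
#' effects (`~ Normal(0, session_sd)`). Sessions 1–2 belong to day 1,
#' sessions 3–4 to day 2.
#'
#' @param subject a [virtual_subject()].
#' @return list with numeric vectors `day` (length 2) and `session`
#'   (length 4).
#' @export
draw_session_effects <- function(subject) {
  stopifnot(inherits(subject, "virtual_subject"))
  list(day = stats::rnorm(2, 0, subject$day_sd),
       session = stats::rnorm(4, 0, subject$session_sd))
}

#' Session-realised threshold
#'
#' The effective threshold for a given session:
#' `true_threshold + day_effect(day(session)) + session_effect(session)`,
#' with effects drawn once per subject via [draw_session_effects()] and
#' shared across sessions of the same day.
#'
#' @param subject a [virtual_subject()].
#' @param session session index in 1–4.
#' @param effects a [draw_session_effects()] draw.
#' @return the realised threshold (\%MSO).
#' @examples
#' vs <- virtual_subject(50, day_sd = 0, session_sd = 0)
#' realize_session_threshold(vs, 1, draw_session_effects(vs))  # 50
#' @export
realize_session_threshold <- function(subject, session, effects) {
  stopifnot(inherits(subject, "virtual_subject"),
            session %in% 1:4,
            is.list(effects), length(effects$day) == 2L,
            length(effects$session) == 4L)
  day <- if (session <= 2) 1L else 2L
  subject$true_threshold + effects$day[day] + effects$session[session]
}
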