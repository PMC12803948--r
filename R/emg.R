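#' Single-trial EMG trace
#'
#' Container for one stimulus-locked surface-EMG sweep. Sample times are
#' defined relative to the stimulus: sample `stimulus_index` is at 0 ms.
#' For full evaluation (artifact rejection + MEP measurement) the trace
#' must span at least 65 ms before and 40 ms after the stimulus.
#'
#' @param samples numeric vector of amplitudes in mV.
#' @param sampling_rate sampling rate in Hz (default 5000).
#' @param stimulus_index 1-based sample index of stimulus onset.
#' @return an object of class `"emg_trace"`.
#' @export
emg_trace <- function(samples, sampling_rate = 5000, stimulus_index) {
  stopifnot(is.numeric(samples), length(samples) > 0,
            is.numeric(sampling_rate), sampling_rate > 0,
            stimulus_index >= 1, stimulus_index <= length(samples))
  structure(list(samples = as.numeric(samples),
                 sampling_rate = sampling_rate,
                 stimulus_index = as.integer(stimulus_index)),
            class = "emg_trace")
}

#' @export
print.emg_trace <- function(x, ...) {
  n <- length(x$samples)
  pre <- (x$stimulus_index - 1) / x$sampling_rate * 1000
  post <- (n - x$stimulus_index) / x$sampling_rate * 1000
  cat(sprintf("EMG trace: %d samples @ %g Hz (%.1f ms pre, %.1f ms post)\n",
              n, x$sampling_rate, pre, post))
  invisible(x)
}

#' Evaluation windows and cutoffs for trial classification
#'
#' Defaults follow the standard online protocol: trials with more than
#' 0.05 mV peak-to-peak voluntary EMG in the 65 ms before the stimulus
#' are rejected; the MEP is measured as the peak-to-peak amplitude in
#' the 15–40 ms post-stimulus window.
#'
#' @param pre_artifact_ms length of the pre-stimulus rejection window (ms).
#' @param mep_start_ms,mep_end_ms MEP measurement window bounds (ms after
#'   stimulus), both inclusive at sample resolution.
#' @param artifact_cutoff_mv rejection cutoff (mV peak-to-peak, strict).
#' @return a list of class `"window_spec"`.
#' @export
window_spec <- function(pre_artifact_ms = 65, mep_start_ms = 15,
                        mep_end_ms = 40, artifact_cutoff_mv = 0.05) {
  stopifnot(pre_artifact_ms > 0, mep_start_ms > 0,
            mep_start_ms < mep_end_ms, artifact_cutoff_mv > 0)
  structure(list(pre_artifact_ms = pre_artifact_ms,
                 mep_start_ms = mep_start_ms,
                 mep_end_ms = mep_end_ms,
                 artifact_cutoff_mv = artifact_cutoff_mv),
            class = "window_spec")
}

# sample indices whose time (ms relative to stimulus) lies in the window.
# Endpoints are converted by rounding to the nearest sample; the window
# is closed at both ends unless right_open, which drops the end sample
# (used for the [-65, 0) rejection window).
.window_idx <- function(trace, from_ms, to_ms, right_open = FALSE) {
  step <- 1000 / trace$sampling_rate
  i0 <- trace$stimulus_index + round(from_ms / step)
  i1 <- trace$stimulus_index + round(to_ms / step)
  if (right_open) i1 <- i1 - 1L
  if (i0 < 1 || i1 > length(trace$samples)) {
    stop("window [", from_ms, ", ", to_ms, "] ms lies outside the trace",
         call. = FALSE)
  }
  seq.int(i0, i1)
}

#' Peak-to-peak amplitude in a time window
#'
#' @param trace an [emg_trace()].
#' @param window numeric length-2 vector, window bounds in ms relative to
#'   the stimulus (closed at both ends at sample resolution).
#' @return max minus min of the samples in the window (mV).
#' @examples
#' tr <- emg_trace(c(rep(0, 400), 0.3, -0.1, rep(0, 200)),
#'                 stimulus_index = 350)
#' peak_to_peak(tr, c(0, 35))
#' @export
peak_to_peak <- function(trace, window) {
  stopifnot(inherits(trace, "emg_trace"), length(window) == 2L,
            window[1] < window[2])
  s <- trace$samples[.window_idx(trace, window[1], window[2])]
  max(s) - min(s)
}

#' Online artifact rejection test
#'
#' A trial is rejected when the peak-to-peak amplitude of voluntary EMG
#' in the pre-stimulus window (default the 65 ms before the stimulus,
#' taken as `[-65, 0)` ms) strictly exceeds the cutoff (default
#' 0.05 mV).
#'
#' @param trace an [emg_trace()].
#' @param spec a [window_spec()].
#' @return logical.
#' @export
is_rejected <- function(trace, spec = window_spec()) {
  stopifnot(inherits(trace, "emg_trace"))
  idx <- .window_idx(trace, -spec$pre_artifact_ms, 0, right_open = TRUE)
  s <- trace$samples[idx]
  (max(s) - min(s)) > spec$artifact_cutoff_mv
}

#' Classify a stimulation trial from its EMG trace
#'
#' Applies the online pipeline: pre-stimulus artifact rejection first;
#' otherwise the trial is a success if the MEP-window peak-to-peak
#' amplitude is strictly greater than the target amplitude. A
#' peak-to-peak exactly equal to the target counts as a failure.
#'
#' @param trace an [emg_trace()].
#' @param target_amplitude MEP success cutoff in mV (typically 0.05 or
#'   0.2).
#' @param spec a [window_spec()].
#' @return one of `"success"`, `"failure"`, `"rejected"`.
#' @export
classify_trial <- function(trace, target_amplitude = 0.05,
                           spec = window_spec()) {
  stopifnot(is.numeric(target_amplitude), target_amplitude > 0)
  if (is_rejected(trace, spec)) return("rejected")
  amp <- peak_to_peak(trace, c(spec$mep_start_ms, spec$mep_end_ms))
  if (amp > target_amplitude) "success" else "failure"
}

#' Read / write an EMG trace as CSV
#'
#' A minimal plain-text dialect: leading comment lines
#' `# sampling_rate: <Hz>` and `# stimulus_index: <i>`, then one header
#' line `amplitude_mv` and one sample per row.
#'
#' @param path file path.
#' @return `read_emg_csv` returns an [emg_trace()];
#'   `write_emg_csv` returns `path` invisibly.
#' @export
read_emg_csv <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  get <- function(key) {
    m <- grep(paste0("^#\\s*", key, "\\s*:"), hdr, value = TRUE)
    if (length(m) != 1L) stop("missing header field '", key, "' in ", path,
                              call. = FALSE)
    as.numeric(sub(".*:\\s*", "", m))
  }
  body <- utils::read.csv(text = lines[!grepl("^#", lines)])
  emg_trace(body$amplitude_mv, sampling_rate = get("sampling_rate"),
            stimulus_index = get("stimulus_index"))
}

#' @rdname read_emg_csv
#' @param trace an [emg_trace()].
#' @export
write_emg_csv <- function(trace, path) {
  stopifnot(inherits(trace, "emg_trace"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# sampling_rate: %g", trace$sampling_rate),
               sprintf("# stimulus_index: %d", trace$stimulus_index),
               "amplitude_mv"), con)
  writeLines(sprintf("%.6g", trace$samples), con)
  invisible(path)
}
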