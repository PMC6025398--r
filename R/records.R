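#' ECG record
#'
#' Container for a uniformly sampled single-lead ECG trace.
#'
#' @param samples Numeric vector of voltages (mV). Must be finite, length >= 2.
#' @param fs Sampling rate in Hz (> 0).
#' @param t0 Record start time in seconds (default 0).
#' @param lead Lead label (default "I").
#' @return An object of class `ecg_record`: a list with elements `samples`,
#'   `fs`, `t0`, `lead`.
#' @export
ecg_record <- function(samples, fs, t0 = 0, lead = "I") {
  samples <- as.numeric(samples)
  if (length(samples) < 2L) stop_domain("ECG record needs at least 2 samples")
  if (any(!is.finite(samples))) stop_domain("ECG samples must be finite")
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop_domain("sampling rate fs must be a positive number")
  structure(
    list(samples = samples, fs = as.numeric(fs), t0 = as.numeric(t0),
         lead = as.character(lead)),
    class = "ecg_record"
  )
}

#' @export
print.ecg_record <- function(x, ...) {
  cat(sprintf("<ecg_record> lead %s, %d samples @ %g Hz (%.1f s), t0 = %g s\n",
              x$lead, length(x$samples), x$fs,
              length(x$samples) / x$fs, x$t0))
  invisible(x)
}

#' @export
length.ecg_record <- function(x) length(x$samples)

#' RR interval series
#'
#' Ordered inter-beat intervals in milliseconds, optionally with the absolute
#' time (seconds) of each interval's *terminal* beat, per-interval validity
#' flags and the rejection reason assigned by [filter_rr()].
#'
#' @param intervals Numeric vector of intervals (ms), all > 0.
#' @param beat_times Optional numeric vector, same length: time (s) of the
#'   terminal beat of each interval; strictly increasing.
#' @param valid Logical vector or NA (validity unknown until filtering).
#' @param rejection_reason Character vector over
#'   `c("none","abs_low","abs_high","delta_jump","rel_change")`, or NA.
#' @return An object of class `rr_series`.
#' @export
rr_series <- function(intervals, beat_times = NULL, valid = NA,
                      rejection_reason = NA_character_) {
  intervals <- as.numeric(intervals)
  if (length(intervals) == 0L) stop_domain("empty RR series")
  if (any(!is.finite(intervals)) || any(intervals <= 0))
    stop_format("RR intervals must be positive finite numbers (ms)")
  if (!is.null(beat_times)) {
    beat_times <- as.numeric(beat_times)
    if (length(beat_times) != length(intervals))
      stop_domain("beat_times must have one entry per interval")
    if (any(diff(beat_times) <= 0))
      stop_domain("beat_times must be strictly increasing")
  }
  valid <- rep_len(as.logical(valid), length(intervals))
  rejection_reason <- rep_len(as.character(rejection_reason), length(intervals))
  structure(
    list(intervals = intervals, beat_times = beat_times, valid = valid,
         rejection_reason = rejection_reason),
    class = "rr_series"
  )
}

#' @export
print.rr_series <- function(x, ...) {
  nval <- if (all(is.na(x$valid))) "unfiltered" else
    sprintf("%d valid (NN)", sum(x$valid, na.rm = TRUE))
  cat(sprintf("<rr_series> %d intervals, mean %.1f ms, %s\n",
              length(x$intervals), mean(x$intervals), nval))
  invisible(x)
}

#' @export
length.rr_series <- function(x) length(x$intervals)

#' Beat annotations
#'
#' Strictly increasing R-peak times produced by [detect_r_peaks()].
#'
#' @param beat_times Numeric vector of beat times in seconds, strictly
#'   increasing.
#' @param detector_meta Named list of detector parameters.
#' @return An object of class `beat_annotations`.
#' @export
beat_annotations <- function(beat_times, detector_meta = list()) {
  beat_times <- as.numeric(beat_times)
  if (length(beat_times) > 1L && any(diff(beat_times) <= 0))
    stop_domain("beat times must be strictly increasing")
  structure(list(beat_times = beat_times, detector_meta = detector_meta),
            class = "beat_annotations")
}

#' @export
print.beat_annotations <- function(x, ...) {
  cat(sprintf("<beat_annotations> %d beats", length(x$beat_times)))
  if (length(x$beat_times) > 1L)
    cat(sprintf(", mean RR %.0f ms", mean(diff(x$beat_times)) * 1000))
  cat("\n")
  invisible(x)
}

#' Protocol condition labels
#'
#' The four conditions of the acute-stress protocol, in chronological order:
#' resting baseline, pre-stress reaction-time task, the stress task, and the
#' post-stress reaction-time task.
#' @format Character vector of length 4.
#' @export
PROTOCOL_CONDITIONS <- c("baseline", "CRTT1", "TSST", "CRTT2")

#' Event annotations
#'
#' @param label Character vector of condition labels (non-empty strings).
#' @param onset Numeric vector, seconds from record start; non-decreasing.
#' @param duration Optional numeric vector of durations (s); NA allowed.
#' @return A data.frame of class `event_annotations` with columns
#'   `label`, `onset`, `duration`.
#' @export
event_annotations <- function(label, onset, duration = NA_real_) {
  label <- as.character(label)
  onset <- as.numeric(onset)
  if (length(label) != length(onset)) stop_format("label/onset length mismatch")
  if (any(!nzchar(label)) || anyNA(label)) stop_format("event labels must be non-empty")
  if (is.unsorted(onset)) stop_format("event onsets must be non-decreasing")
  out <- data.frame(label = label, onset = onset,
                    duration = rep_len(as.numeric(duration), length(label)),
                    stringsAsFactors = FALSE)
  class(out) <- c("event_annotations", "data.frame")
  out
}
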