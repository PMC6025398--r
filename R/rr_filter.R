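## Physiological validity filtering of RR intervals.
##
## An interval is removed iff it (a) lies outside [abs_low, abs_high] ms
## (strict inequalities: the boundaries are kept), (b) changed by more than
## max_delta ms with respect to the previous VALID interval, or (c) deviates
## by more than max_rel (fraction) from the mean of the last rel_window
## VALID intervals. The reference state updates online within one forward
## pass: a rejected interval never becomes a reference. Rules (b)/(c) are
## skipped, not failed, while insufficient valid history exists. Surviving
## intervals are the NN (normal-to-normal) intervals.

REJECTION_REASONS <- c("none", "abs_low", "abs_high", "delta_jump", "rel_change")

#' Default RR validity-filter parameters
#'
#' Absolute range 300-3000 ms, maximum jump 400 ms against the previous
#' valid interval, maximum relative deviation 25% against the mean of the
#' last five valid intervals.
#'
#' @return Named list `abs_low`, `abs_high`, `max_delta` (ms), `max_rel`
#'   (fraction), `rel_window` (count).
#' @export
rr_filter_params <- function() {
  list(abs_low = 300, abs_high = 3000, max_delta = 400,
       max_rel = 0.25, rel_window = 5L)
}

#' Filter RR intervals for physiological validity
#'
#' @param rr An [rr_series()] (nonempty).
#' @param params Parameter list as from [rr_filter_params()]; partial lists
#'   are merged over the defaults. Setting `max_delta` and `max_rel` to `Inf`
#'   reduces the filter to pure absolute-range clipping.
#' @return The input series with `valid` and `rejection_reason` filled in.
#'   Each invalid interval carries the *first* rule it violated, in the
#'   order absolute range, delta jump, relative change.
#' @export
filter_rr <- function(rr, params = rr_filter_params()) {
  stopifnot(inherits(rr, "rr_series"))
  p <- utils::modifyList(rr_filter_params(), params)
  with(p, {
    if (abs_low <= 0 || abs_high <= 0 || max_delta <= 0 || max_rel <= 0 ||
        rel_window <= 0)
      stop_config("filter parameters must be positive")
    if (abs_low >= abs_high) stop_config("abs_low must be below abs_high")
  })
  iv <- rr$intervals
  n <- length(iv)
  valid <- logical(n)
  reason <- rep("none", n)
  hist <- numeric(0)   # valid intervals so far, oldest first
  for (i in seq_len(n)) {
    x <- iv[i]
    if (x < p$abs_low) {
      reason[i] <- "abs_low"
    } else if (x > p$abs_high) {
      reason[i] <- "abs_high"
    } else if (length(hist) >= 1L &&
               abs(x - hist[length(hist)]) > p$max_delta) {
      reason[i] <- "delta_jump"
    } else if (length(hist) >= p$rel_window &&
               abs(x - mean(utils::tail(hist, p$rel_window))) >
                 p$max_rel * mean(utils::tail(hist, p$rel_window))) {
      reason[i] <- "rel_change"
    } else {
      valid[i] <- TRUE
      hist <- c(hist, x)
    }
  }
  out <- rr
  out$valid <- valid
  out$rejection_reason <- reason
  out
}

#' Extract NN intervals
#'
#' Returns exactly the valid-flagged intervals of a filtered series, in
#' order; invalid intervals are dropped, never interpolated, so downstream
#' spectral analysis must tolerate the resulting gaps.
#'
#' @param rr An [rr_series()] that has been through [filter_rr()].
#' @return A list with `intervals` (ms) and `beat_times` (s, terminal beat
#'   of each NN interval; `NULL` if the input had no beat times). An
#'   all-invalid series yields empty vectors with a warning.
#' @export
nn_intervals <- function(rr) {
  stopifnot(inherits(rr, "rr_series"))
  if (anyNA(rr$valid)) stop_state("series is unfiltered: run filter_rr() first")
  keep <- rr$valid
  if (!any(keep)) warning("no valid NN intervals remain after filtering")
  list(intervals = rr$intervals[keep],
       beat_times = if (is.null(rr$beat_times)) NULL else rr$beat_times[keep])
}

#' Rejection report
#'
#' @param rr A filtered [rr_series()].
#' @return data.frame `index,interval_ms,reason` for the rejected intervals.
#' @export
rejection_report <- function(rr) {
  stopifnot(inherits(rr, "rr_series"))
  if (anyNA(rr$valid)) stop_state("series is unfiltered: run filter_rr() first")
  bad <- which(!rr$valid)
  data.frame(index = bad, interval_ms = rr$intervals[bad],
             reason = rr$rejection_reason[bad])
}
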