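## Scoring of the 2-choice reaction-time task (global/local letter
## discrimination). Key mapping: '1' answers a congruent stimulus, '3' an
## incongruent one. Accuracy = correct / answered (missed trials excluded
## from the denominator); the central tendency of RT is the median over
## answered trials, because RT distributions are right-skewed.

#' Classify a trial response
#'
#' @param stimulus Character vector over `c("congruent", "incongruent")`.
#' @param response_key Character vector over `c("1", "3")` or `NA` (no
#'   response). Any other token is a format error.
#' @return Character vector over `c("correct", "incorrect", "missed")`:
#'   congruent+'1' and incongruent+'3' are correct, any other answered
#'   combination incorrect, no key missed.
#' @export
classify_response <- function(stimulus, response_key) {
  if (!all(stimulus %in% c("congruent", "incongruent")))
    stop_format("unknown stimulus token")
  bad <- !is.na(response_key) & !response_key %in% c("1", "3")
  if (any(bad))
    stop_format(paste("unknown response key token:",
                      paste(unique(response_key[bad]), collapse = ", ")))
  expected <- ifelse(stimulus == "congruent", "1", "3")
  ifelse(is.na(response_key), "missed",
         ifelse(response_key == expected, "correct", "incorrect"))
}

#' Score a CRTT trial log
#'
#' @param log A `crtt_log` data.frame (see [read_crtt_log()]) with columns
#'   `stimulus`, `response_key`, `rt_ms`, `outcome`.
#' @param rt_trials `"answered"` (default: median RT over all answered
#'   trials, correct and incorrect) or `"correct"` (correct trials only).
#' @return list of class `crtt_summary`: `median_rt_ms`, `accuracy`
#'   (proportion in [0, 1]), `n_answered`, `n_correct`, `n_missed`,
#'   `n_trials`. Zero answered trials is an error.
#' @export
score_crtt <- function(log, rt_trials = c("answered", "correct")) {
  rt_trials <- match.arg(rt_trials)
  need <- c("stimulus", "response_key", "rt_ms", "outcome")
  if (!all(need %in% names(log)))
    stop_format(paste("CRTT log missing columns:",
                      paste(setdiff(need, names(log)), collapse = ", ")))
  if (!all(log$outcome %in% CRTT_OUTCOMES))
    stop_format("unknown outcome token in CRTT log")
  answered <- log$outcome != "missed"
  n_answered <- sum(answered)
  if (n_answered == 0L)
    stop_classed("stresshrv_undefined_summary",
                 "no answered trials: summary undefined")
  n_correct <- sum(log$outcome == "correct")
  rt_pool <- if (rt_trials == "answered") log$rt_ms[answered]
             else log$rt_ms[log$outcome == "correct"]
  structure(
    list(median_rt_ms = stats::median(rt_pool, na.rm = TRUE),
         accuracy = n_correct / n_answered,
         n_answered = n_answered, n_correct = n_correct,
         n_missed = sum(!answered), n_trials = nrow(log)),
    class = "crtt_summary")
}

#' @export
print.crtt_summary <- function(x, ...) {
  cat(sprintf("<crtt_summary> %d trials: median RT %.0f ms, accuracy %.3f (%d/%d answered, %d missed)\n",
              x$n_trials, x$median_rt_ms, x$accuracy,
              x$n_correct, x$n_answered, x$n_missed))
  invisible(x)
}
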