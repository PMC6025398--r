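## Event-synchronised segmentation: map annotations to condition windows,
## cut each window into consecutive non-overlapping complete blocks of
## block_len seconds anchored at the condition onset, and assemble the
## per-subject, per-condition study table.

#' Cut an NN series into per-condition analysis blocks
#'
#' A condition window runs from its onset to its stated duration, or to the
#' next event's onset (or the last beat) when no duration is given. Blocks
#' are half-open `[start, start + block_len)`, anchored at the condition
#' onset; trailing partial blocks are discarded. An NN interval belongs to
#' the block containing its *terminal* beat time, so no interval is ever
#' split across blocks.
#'
#' @param nn A filtered [rr_series()] with beat times, or an
#'   [nn_intervals()] result with beat times.
#' @param events An [event_annotations()] data.frame.
#' @param block_len Block length in seconds (default 300 = 5 min).
#' @return Named list, one element per condition, each a list of blocks;
#'   a block is `list(intervals, beat_times, start, end)`. Conditions
#'   shorter than `block_len` get zero blocks with a warning.
#' @export
segment_blocks <- function(nn, events, block_len = 300) {
  if (inherits(nn, "rr_series")) nn <- nn_intervals(nn)
  if (is.null(nn$beat_times)) stop_domain("segmentation needs beat times")
  if (block_len <= 0) stop_config("block_len must be positive")
  ev <- events[order(events$onset), , drop = FALSE]
  n_ev <- nrow(ev)
  ends <- ifelse(!is.na(ev$duration), ev$onset + ev$duration,
                 c(ev$onset[-1], max(nn$beat_times) + 1e-9))
  if (n_ev > 1L && any(ends[-n_ev] - ev$onset[-1] > 1e-9))
    stop_format("overlapping condition windows in event annotations")

  out <- stats::setNames(vector("list", n_ev), ev$label)
  for (k in seq_len(n_ev)) {
    win <- c(ev$onset[k], ends[k])
    n_blocks <- floor((win[2] - win[1]) / block_len)
    if (n_blocks == 0L)
      warning(sprintf("condition '%s' (%.0f s) is shorter than one %.0f s block",
                      ev$label[k], win[2] - win[1], block_len))
    blocks <- vector("list", n_blocks)
    for (j in seq_len(n_blocks)) {
      b0 <- win[1] + (j - 1) * block_len
      b1 <- b0 + block_len
      sel <- nn$beat_times >= b0 & nn$beat_times < b1
      blocks[[j]] <- list(intervals = nn$intervals[sel],
                          beat_times = nn$beat_times[sel],
                          start = b0, end = b1)
    }
    out[[k]] <- blocks
  }
  out
}

#' Assemble the per-subject, per-condition study table
#'
#' Per-condition feature values are arithmetic means over that subject's
#' blocks. Subjects lacking blocks (or features) for some condition get NA
#' cells and `complete = FALSE`; such subjects are excluded from paired
#' tests downstream.
#'
#' @param block_features data.frame with columns `subject`, `condition`,
#'   `block` and the [extract_block_features()] feature columns (one row per
#'   block). Duplicate `(subject, condition, block)` keys are an error.
#' @param scores Optional data.frame `subject, condition, vas, stai`.
#' @param crtt_summaries Optional data.frame
#'   `subject, condition, median_rt_ms, accuracy`.
#' @param conditions Condition set defining completeness (default
#'   [PROTOCOL_CONDITIONS]).
#' @return data.frame of class `study_frame`, one row per
#'   (subject, condition).
#' @export
build_study_frame <- function(block_features, scores = NULL,
                              crtt_summaries = NULL,
                              conditions = PROTOCOL_CONDITIONS) {
  if (nrow(block_features) < 1L) stop_domain("need at least 1 subject")
  key <- interaction(block_features$subject, block_features$condition,
                     block_features$block, drop = TRUE)
  if (anyDuplicated(key))
    stop_classed("stresshrv_key_error",
                 "duplicate (subject, condition, block) rows in block_features")
  feat_cols <- intersect(
    c("avnn", "sdnn", "rmssd", "pnnx", "lf_power", "hf_power", "lf_hf"),
    names(block_features))
  subjects <- unique(block_features$subject)
  grid <- expand.grid(subject = subjects, condition = conditions,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  agg <- stats::aggregate(block_features[feat_cols],
                          by = list(subject = block_features$subject,
                                    condition = block_features$condition),
                          FUN = mean, na.rm = TRUE)
  nblk <- stats::aggregate(list(n_blocks = block_features$block),
                           by = list(subject = block_features$subject,
                                     condition = block_features$condition),
                           FUN = length)
  out <- merge(grid, merge(agg, nblk), by = c("subject", "condition"),
               all.x = TRUE, sort = FALSE)
  out$n_blocks[is.na(out$n_blocks)] <- 0L
  if (!is.null(scores))
    out <- merge(out, scores, by = c("subject", "condition"),
                 all.x = TRUE, sort = FALSE)
  if (!is.null(crtt_summaries))
    out <- merge(out, crtt_summaries, by = c("subject", "condition"),
                 all.x = TRUE, sort = FALSE)
  out <- out[order(match(out$subject, subjects),
                   match(out$condition, conditions)), , drop = FALSE]
  rownames(out) <- NULL
  complete_by_subject <- tapply(out$n_blocks >= 1, out$subject, all)
  out$complete <- as.logical(complete_by_subject[as.character(out$subject)])
  out$condition <- factor(out$condition, levels = conditions)
  class(out) <- c("study_frame", "data.frame")
  out
}

#' Wide matrix for one measure
#'
#' Subjects x conditions matrix of one study-frame measure; optionally
#' restricted to complete cases.
#'
#' @param frame A `study_frame`.
#' @param measure Column name, e.g. `"avnn"`.
#' @param complete_only Drop subjects with any NA in the measure.
#' @return Numeric matrix, rownames = subjects, colnames = conditions.
#' @export
measure_matrix <- function(frame, measure, complete_only = TRUE) {
  if (!measure %in% names(frame)) stop_config(paste("no such measure:", measure))
  m <- tapply(frame[[measure]], list(frame$subject, frame$condition), mean)
  m <- matrix(as.numeric(m), nrow = nrow(m), dimnames = dimnames(m))
  if (complete_only) m <- m[stats::complete.cases(m), , drop = FALSE]
  m
}
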