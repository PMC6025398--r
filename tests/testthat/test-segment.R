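make_nn <- function(duration, mean_rr = 800, t0 = 0) {
  n <- ceiling(duration * 1000 / mean_rr) + 1
  iv <- rep(mean_rr, n)
  bt <- t0 + cumsum(iv) / 1000
  keep <- bt <= t0 + duration
  rr <- rr_series(iv[keep], beat_times = bt[keep], valid = TRUE,
                  rejection_reason = "none")
  rr
}

test_that("a 10-min condition yields exactly two 5-min blocks", {
  nn <- make_nn(600)
  ev <- event_annotations("TSST", 0, 600)
  blocks <- segment_blocks(nn, ev)
  expect_length(blocks$TSST, 2)
  expect_equal(blocks$TSST[[1]]$start, 0)
  expect_equal(blocks$TSST[[2]]$start, 300)
})

test_that("short and ragged conditions follow the floor rule", {
  nn <- make_nn(720)
  expect_warning(
    b4 <- segment_blocks(nn, event_annotations("baseline", 0, 240)),
    "shorter")
  expect_length(b4$baseline, 0)

  b12 <- segment_blocks(nn, event_annotations("TSST", 0, 720))
  expect_length(b12$TSST, 2)   # floor(720/300); 120 s remainder discarded
})

test_that("block membership follows the terminal beat and never splits intervals", {
  nn <- make_nn(600)
  ev <- event_annotations("TSST", 0, 600)
  blocks <- segment_blocks(nn, ev)
  all_bt <- c(blocks$TSST[[1]]$beat_times, blocks$TSST[[2]]$beat_times)
  expect_false(any(duplicated(all_bt)))
  expect_true(all(blocks$TSST[[1]]$beat_times < 300))
  expect_true(all(blocks$TSST[[2]]$beat_times >= 300))
  # interval sums bounded by condition counts
  expect_lte(length(all_bt), length(nn$intervals))
})

test_that("windows bound by the next onset; overlaps are rejected", {
  nn <- make_nn(1200)
  ev <- event_annotations(c("baseline", "CRTT1"), c(0, 600))
  blocks <- segment_blocks(nn, ev)
  expect_length(blocks$baseline, 2)
  bad <- event_annotations(c("baseline", "CRTT1"), c(0, 500), c(600, 600))
  expect_error(segment_blocks(nn, bad), class = "stresshrv_format_error")
})

test_that("build_study_frame averages blocks and flags incomplete subjects", {
  bf <- data.frame(
    subject = rep(c("S01", "S02"), each = 8),
    condition = rep(rep(PROTOCOL_CONDITIONS, each = 2), 2),
    block = rep(1:2, 8),
    avnn = c(700, 710, 720, 730, 650, 660, 700, 720,
             800, 820, 790, 810, 700, 720, 805, 815))
  frame <- build_study_frame(bf)
  expect_s3_class(frame, "study_frame")
  expect_equal(nrow(frame), 8)
  expect_equal(frame$avnn[frame$subject == "S01" &
                            frame$condition == "baseline"], 705)
  expect_true(all(frame$complete))

  # missing TSST: flagged incomplete, NA cell
  bf2 <- bf[!(bf$subject == "S02" & bf$condition == "TSST"), ]
  frame2 <- build_study_frame(bf2)
  expect_equal(nrow(frame2), 8)
  expect_false(any(frame2$complete[frame2$subject == "S02"]))
  expect_true(is.na(frame2$avnn[frame2$subject == "S02" &
                                  frame2$condition == "TSST"]))
  # incomplete subjects are dropped from paired analyses
  expect_equal(nrow(measure_matrix(frame2, "avnn")), 1)

  # duplicate keys are an error
  expect_error(build_study_frame(rbind(bf, bf[1, ])),
               class = "stresshrv_key_error")
})

test_that("synthetic 11-subject cohort gives a 44-row frame", {
  spec <- default_cohort_spec(n_subjects = 3, condition_len = 600)
  cohort <- generate_cohort(spec, seed = 7)
  feats <- do.call(rbind, lapply(cohort$subjects, function(s)
    analyze_subject(s$rr, s$events, subject = s$subject)))
  frame <- build_study_frame(feats)
  expect_equal(nrow(frame), 3 * 4)   # n_subjects x 4 conditions
  expect_true(all(frame$n_blocks == 2))
})
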