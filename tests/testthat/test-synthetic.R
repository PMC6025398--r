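test_that("IPFM beat count and determinism", {
  st <- autonomic_state(800, sd_rr = 0, a_lf = 0, a_hf = 0, duration = 300)
  rr <- generate_rr(st, seed = 1)
  expect_equal(length(rr$intervals), 375)           # floor(300000/800)
  expect_true(all(abs(rr$intervals - 800) < 1e-6))

  rr2 <- generate_rr(st, seed = 1)
  expect_identical(rr$intervals, rr2$intervals)     # same seed, same series

  st2 <- autonomic_state(700, sd_rr = 3, a_lf = 0.05, a_hf = 0.02,
                         duration = 200)
  a <- generate_rr(st2, seed = 9); b <- generate_rr(st2, seed = 9)
  expect_identical(a$intervals, b$intervals)
  expect_false(identical(generate_rr(st2, seed = 10)$intervals, a$intervals))
})

test_that("invalid autonomic states are rejected", {
  expect_error(autonomic_state(800, a_lf = 0.6, a_hf = 0.5),
               class = "stresshrv_config_error")
  expect_error(autonomic_state(200), class = "stresshrv_config_error")
  expect_error(autonomic_state(800, f_lf = 0.2), class = "stresshrv_config_error")
})

test_that("LF/HF input power ratio is recovered from generated series", {
  # amplitude ratio 2 -> power ratio 4
  st <- autonomic_state(800, sd_rr = 1, a_lf = 0.06, a_hf = 0.03,
                        duration = 600)
  set.seed(14)
  est <- replicate(10, {
    rr <- generate_rr(st)
    lf_hf(rr$intervals, rr$beat_times)$lf_hf
  })
  truth <- attr(generate_rr(st, seed = 1), "ground_truth")$lfhf_interval
  expect_equal(mean(est), truth, tolerance = 0.10)
})

test_that("ECG rendering places R peaks at the beat times", {
  rr <- generate_rr(autonomic_state(750, sd_rr = 5, a_lf = 0.02, a_hf = 0.02,
                                    duration = 60), seed = 3)
  ecg <- generate_ecg(rr, fs = 250)
  truth <- attr(ecg, "true_beats")
  expect_equal(length(truth), length(rr$intervals) + 1)
  # signal peaks within 10 ms of each true beat
  tt <- (seq_along(ecg$samples) - 1) / ecg$fs
  for (b in truth[2:10]) {
    win <- which(abs(tt - b) <= 0.05)
    expect_lt(abs(tt[win[which.max(ecg$samples[win])]] - b), 0.01)
  }

  flat <- generate_ecg(rr, fs = 250,
                       template = transform(pqrst_template(), amp = 0))
  expect_true(all(abs(flat$samples) < 1e-12))

  expect_error(generate_ecg(rr, fs = 80), class = "stresshrv_rate_error")
})

test_that("artifact injection is mapped and caught by the filter", {
  rr <- rr_series(rep(800, 100), beat_times = cumsum(rep(800, 100)) / 1000)

  ident <- inject_artifacts(rr, 0, 0, seed = 1)
  expect_equal(ident$intervals, rr$intervals)
  expect_equal(nrow(attr(ident, "corruption_map")), 0)

  # a single merged pair becomes a 1600 ms interval the delta rule rejects
  merged <- rr_series(c(rep(800, 10), 1600, rep(800, 10)))
  f <- filter_rr(merged)
  expect_false(f$valid[11])
  expect_equal(f$rejection_reason[11], "delta_jump")

  expect_error(inject_artifacts(rr, 0.5, 0), class = "stresshrv_config_error")

  # filter recall >= 90% on 5-min series at default rates
  st <- calibrate_autonomic_state(800, 25, 2.5, sd_rr = 4, duration = 300)
  set.seed(31)
  recalls <- replicate(10, {
    clean <- generate_rr(st)
    bad <- inject_artifacts(clean, 0.02, 0.02)
    map <- attr(bad, "corruption_map")
    filt <- filter_rr(bad)
    mean(!filt$valid[map$index])
  })
  expect_gte(mean(recalls), 0.90)
})

test_that("cohort generation: structure, determinism, CRTT constraints", {
  spec <- default_cohort_spec(n_subjects = 4, condition_len = 600)
  cohort <- generate_cohort(spec, seed = 5)
  expect_length(cohort$subjects, 4)
  expect_equal(nrow(cohort$ground_truth), 16)        # 4 x 4 conditions
  expect_equal(sum(vapply(cohort$subjects,
                          function(s) length(s$crtt), integer(1))), 8)

  again <- generate_cohort(spec, seed = 5)
  expect_identical(cohort$subjects[[2]]$rr$intervals,
                   again$subjects[[2]]$rr$intervals)
  expect_identical(cohort$subjects[[3]]$crtt$CRTT1$rt_ms,
                   again$subjects[[3]]$crtt$CRTT1$rt_ms)

  for (s in cohort$subjects) {
    expect_equal(s$events$label, PROTOCOL_CONDITIONS)
    for (log in s$crtt) {
      isi <- diff(log$onset_s)
      expect_true(all(isi >= 3 - 1e-9 & isi <= 10 + 1e-9))
      expect_true(all(log$display_ms >= 100 & log$display_ms <= 500))
      frac_con <- mean(log$stimulus == "congruent")
      expect_lte(abs(frac_con - 0.5), 1 / nrow(log))
    }
    expect_true(all(s$scores$vas >= 0 & s$scores$vas <= 10))
  }
})

test_that("pre/post RT association is strong and negative on synthetic cohorts", {
  cohort <- generate_cohort(default_cohort_spec(), seed = 2)
  rt <- t(vapply(cohort$subjects, function(s)
    c(score_crtt(s$crtt$CRTT1)$median_rt_ms,
      score_crtt(s$crtt$CRTT2)$median_rt_ms), numeric(2)))
  res <- spearman_test(rt[, 1], rt[, 2], exact_n_max = 8)
  expect_lt(res$statistic, -0.5)   # sign/strength pattern, not magnitude
})

test_that("cohort round-trips through the on-disk layout", {
  dir <- withr::local_tempdir()
  spec <- default_cohort_spec(n_subjects = 2, condition_len = 600)
  cohort <- generate_cohort(spec, seed = 8)
  write_cohort(cohort, dir)
  expect_true(file.exists(file.path(dir, "ground_truth.csv")))
  rr_back <- read_rr(file.path(dir, "S01_rr.csv"))
  expect_equal(rr_back$intervals, cohort$subjects[[1]]$rr$intervals,
               tolerance = 1e-9)
  log_back <- read_crtt_log(file.path(dir, "S02_crtt1.csv"))
  expect_equal(log_back$outcome, cohort$subjects[[2]]$crtt$CRTT1$outcome)
})
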