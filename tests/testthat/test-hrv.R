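test_that("time-domain features match hand arithmetic and naive oracles", {
  expect_equal(avnn(c(800, 800, 800)), 800)
  expect_equal(avnn(c(600, 700, 800)), 700)
  expect_error(avnn(numeric(0)), class = "stresshrv_domain_error")

  expect_equal(sdnn(rep(750, 10)), 0)
  expect_equal(sdnn(c(700, 900)), 100)           # population denominator
  expect_equal(sdnn(c(700, 900), population = FALSE), sd(c(700, 900)))
  expect_error(sdnn(800), class = "stresshrv_domain_error")

  expect_equal(rmssd(rep(640, 5)), 0)
  expect_equal(rmssd(c(700, 720, 700)), 20)      # sqrt((400+400)/2)
  expect_error(rmssd(800), class = "stresshrv_domain_error")

  set.seed(3)
  x <- runif(10000, 400, 1400)
  expect_equal(sdnn(x), oracle_sd_pop(x), tolerance = 1e-9)
  expect_equal(rmssd(x), sqrt(mean(diff(x)^2)), tolerance = 1e-12)
})

test_that("pNNx uses strict inequality and the total-NN denominator", {
  expect_equal(pnnx(rep(800, 50)), 0)
  # both successive diffs are 21 > 20; denominator is 3 (total count)
  expect_equal(pnnx(c(700, 721, 700), x = 20), 100 * 2 / 3, tolerance = 1e-9)
  expect_equal(pnnx(c(700, 721, 700), x = 20, denominator = "pairs"), 100)
  # a diff of exactly x does not count
  expect_equal(pnnx(c(700, 720, 700), x = 20), 0)
  expect_error(pnnx(c(700, 700), x = -1), class = "stresshrv_config_error")
})

test_that("pNNx is non-increasing in x", {
  set.seed(8)
  nn <- rnorm(500, 800, 40)
  xs <- c(5, 10, 20, 35, 50, 80)
  vals <- vapply(xs, function(x) pnnx(nn, x), numeric(1))
  expect_true(all(diff(vals) <= 1e-12))
})

test_that("time-domain features ignore uniform time translation", {
  set.seed(4)
  nn <- rnorm(300, 800, 30)
  t0 <- cumsum(nn) / 1000
  f0 <- extract_block_features(nn, t0)
  f1 <- extract_block_features(nn, t0 + 1234.5)
  expect_equal(f0$avnn, f1$avnn)
  expect_equal(f0$sdnn, f1$sdnn)
  expect_equal(f0$rmssd, f1$rmssd)
  expect_equal(f0$pnnx, f1$pnnx)
})

test_that("single-tone modulations land in the right band", {
  set.seed(6)
  tone <- function(f_mod) {
    n <- 400; mean_rr <- 800
    tt <- cumsum(rep(mean_rr, n)) / 1000
    nn <- mean_rr + 40 * sin(2 * pi * f_mod * tt)
    lf_hf(nn, tt)
  }
  lo <- tone(0.10)
  expect_gte(lo$lf_power / (lo$lf_power + lo$hf_power), 0.95)
  expect_gt(lo$lf_hf, 10)
  hi <- tone(0.30)
  expect_lt(hi$lf_hf, 0.1)
})

test_that("band power is absolute (ms^2): a known sinusoid recovers A^2/2", {
  set.seed(12)
  n <- 600; mean_rr <- 800; A <- 30
  tt <- cumsum(rnorm(n, mean_rr, 5)) / 1000
  nn <- mean_rr + A * sin(2 * pi * 0.1 * tt) + rnorm(n, 0, 2)
  res <- lf_hf(nn, tt)
  expect_equal(res$lf_power, A^2 / 2, tolerance = 0.15)
})

test_that("lomb and resampled-welch agree on gap-free series", {
  st <- calibrate_autonomic_state(700, 25, 3, sd_rr = 4, duration = 300)
  set.seed(13)
  ratios <- replicate(8, {
    rr <- generate_rr(st)
    a <- lf_hf(rr$intervals, rr$beat_times, method = "lomb")$lf_hf
    b <- lf_hf(rr$intervals, rr$beat_times, method = "welch")$lf_hf
    b / a
  })
  expect_lt(abs(mean(ratios) - 1), 0.15)
})

test_that("lomb tolerates the gaps the filter leaves", {
  st <- calibrate_autonomic_state(700, 25, 3, sd_rr = 4, duration = 300)
  rr <- generate_rr(st, seed = 21)
  drop <- seq(20, length(rr$intervals), by = 17)   # knock out ~6% of beats
  nn <- rr$intervals[-drop]; tt <- rr$beat_times[-drop]
  res <- lf_hf(nn, tt)
  full <- lf_hf(rr$intervals, rr$beat_times)
  expect_equal(res$lf_hf, full$lf_hf, tolerance = 0.25)
})

test_that("spectral preconditions and degenerate blocks", {
  expect_error(lf_hf(rep(800, 10), cumsum(rep(0.8, 10))),
               class = "stresshrv_domain_error")      # too few intervals
  expect_error(lf_hf(rnorm(40, 800, 10), seq(0, 30, length.out = 40)),
               class = "stresshrv_domain_error")      # span too short

  # constant 5-min block: time-domain zeros, spectral flagged not thrown
  nnc <- rep(800, 375)
  f <- extract_block_features(nnc, cumsum(nnc) / 1000)
  expect_equal(f$avnn, 800)
  expect_equal(f$sdnn, 0)
  expect_equal(f$rmssd, 0)
  expect_equal(f$pnnx, 0)
  expect_true(is.na(f$lf_hf) && !is.na(f$spectral_error))

  # 10-interval block: time domain reported, spectral error recorded
  f10 <- extract_block_features(rnorm(10, 800, 20), cumsum(rep(0.8, 10)))
  expect_false(is.na(f10$avnn))
  expect_match(f10$spectral_error, "30 NN")
})
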