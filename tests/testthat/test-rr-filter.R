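test_that("stated rule examples filter as the hand oracle says", {
  # absolute rule
  f1 <- filter_rr(rr_series(c(800, 810, 250, 805)))
  expect_equal(f1$valid, c(TRUE, TRUE, FALSE, TRUE))
  expect_equal(f1$rejection_reason[3], "abs_low")
  expect_length(nn_intervals(f1)$intervals, 3)

  # nothing fires on a constant series
  f2 <- filter_rr(rr_series(rep(800, 100)))
  expect_true(all(f2$valid))

  # delta rule references the most recent VALID interval
  f3 <- filter_rr(rr_series(c(700, 705, 710, 700, 705, 1200, 705)))
  expect_equal(which(!f3$valid), 6L)
  expect_equal(f3$rejection_reason[6], "delta_jump")
  expect_length(nn_intervals(f3)$intervals, 6)
})

test_that("boundary values are kept, strict violations removed", {
  # exact boundaries survive (strict inequalities)
  fb <- filter_rr(rr_series(c(300, 3000)), params = list(max_delta = Inf,
                                                         max_rel = Inf))
  expect_true(all(fb$valid))
  fb2 <- filter_rr(rr_series(c(299.99, 3000.01)))
  expect_equal(fb2$rejection_reason, c("abs_low", "abs_high"))

  # delta boundary: exactly 400 kept, above removed
  fd <- filter_rr(rr_series(c(800, 1200, 800, 1200.5)))
  expect_equal(fd$valid, c(TRUE, TRUE, TRUE, FALSE))
  expect_equal(fd$rejection_reason[4], "delta_jump")

  # relative boundary: exactly 25% kept (1000 vs mean 800), above removed
  fr <- filter_rr(rr_series(c(rep(800, 5), 1000)),
                  params = list(max_delta = Inf))
  expect_true(all(fr$valid))
  fr2 <- filter_rr(rr_series(c(rep(800, 5), 1000.5)),
                   params = list(max_delta = Inf))
  expect_equal(fr2$rejection_reason[6], "rel_change")
})

test_that("filter agrees with the literal oracle on random corrupted series", {
  set.seed(42)
  for (rep in 1:20) {
    n <- sample(20:120, 1)
    iv <- rnorm(n, 800, 60)
    bad <- sample(n, max(1, n %/% 10))
    iv[bad] <- sample(c(150, 280, 1500, 3200, 400), length(bad), replace = TRUE)
    iv <- pmax(iv, 50)
    got <- filter_rr(rr_series(iv))
    expect_equal(got$valid, oracle_filter_rr(iv))
  }
})

test_that("filter is idempotent and NN intervals always lie in [300, 3000]", {
  set.seed(9)
  for (rep in 1:10) {
    iv <- pmax(50, rnorm(200, 800, 300))
    f1 <- filter_rr(rr_series(iv))
    nn1 <- nn_intervals(f1)$intervals
    expect_true(all(nn1 >= 300 & nn1 <= 3000))
    f2 <- filter_rr(rr_series(nn1))
    expect_true(all(f2$valid))  # refiltering the NN series removes nothing
  }
})

test_that("with infinite delta/rel the filter is pure range clipping", {
  set.seed(5)
  iv <- pmax(50, rnorm(500, 900, 600))
  f <- filter_rr(rr_series(iv), params = list(max_delta = Inf, max_rel = Inf))
  expect_equal(f$valid, iv >= 300 & iv <= 3000)
})

test_that("contract errors", {
  expect_error(filter_rr(rr_series(800), params = list(abs_low = -1)),
               class = "stresshrv_config_error")
  unf <- rr_series(c(800, 810))
  expect_error(nn_intervals(unf), class = "stresshrv_state_error")
  allbad <- filter_rr(rr_series(c(100, 100)))
  expect_warning(nn <- nn_intervals(allbad), "no valid")
  expect_length(nn$intervals, 0)
})

test_that("rejection report lists index, interval and first-violated rule", {
  f <- filter_rr(rr_series(c(800, 250, 810, 3200)))
  rep <- rejection_report(f)
  expect_equal(rep$index, c(2L, 4L))
  expect_equal(rep$reason, c("abs_low", "abs_high"))
})
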