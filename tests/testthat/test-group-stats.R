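test_that("Friedman: degenerate, exact-vs-brute-force, and power cases", {
  # identical conditions: statistic 0, p 1
  y0 <- matrix(rep(c(5, 7, 9), times = 3), nrow = 3)
  r0 <- friedman_test(y0)
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p_value, 1)

  # exact enumeration equals literal brute force over all (k!)^n tables
  set.seed(101)
  for (rep in 1:3) {
    y <- matrix(rnorm(5 * 3), nrow = 5)
    got <- friedman_test(y)
    expect_equal(got$p_exact, oracle_friedman_exact(y), tolerance = 1e-10)
  }
  # with ties
  yt <- matrix(c(1, 1, 2, 3, 2, 2, 1, 3, 4, 4, 1, 1), nrow = 4)
  expect_equal(friedman_test(yt)$p_exact, oracle_friedman_exact(yt),
               tolerance = 1e-10)

  # strong monotone effect at n = 11 is detected well below 0.001
  set.seed(7)
  y11 <- outer(rep(0, 11), c(0, 10, 20, 30), "+") + rnorm(44, sd = 0.5)
  expect_lt(friedman_test(y11)$p_value, 0.001)

  expect_error(friedman_test(matrix(1:4, 2, 2)),
               class = "stresshrv_domain_error")
  expect_error(friedman_test(matrix(1:3, 1, 3)),
               class = "stresshrv_domain_error")
})

test_that("Wilcoxon signed-rank: exact null, oracle match, approximations", {
  # y = x + c: all differences one-signed, one-sided exact p = 2^-10
  x <- rnorm(10)
  r <- wilcoxon_signed_rank(x + 1, x, alternative = "greater")
  expect_equal(r$p_value, 1 / 1024, tolerance = 1e-12)

  expect_error(wilcoxon_signed_rank(x, x),
               class = "stresshrv_degenerate_test")

  # exact equals literal 2^n enumeration, ties included
  set.seed(33)
  for (rep in 1:5) {
    d <- sample(c(-3, -2, -1, 1, 2, 3, 5), 9, replace = TRUE)
    a <- sample(50:150, 9)   # integer base keeps difference ties exact
    b <- a - d
    got <- wilcoxon_signed_rank(a, b)
    expect_equal(got$p_value, oracle_wilcoxon_exact(d), tolerance = 1e-10)
  }

  # exact and normal approximation agree to ~0.01 at n = 25
  set.seed(12)
  a <- rnorm(25); b <- a + rnorm(25, 0.3)
  pe <- wilcoxon_signed_rank(a, b, exact_n_max = 25)$p_value
  pn <- wilcoxon_signed_rank(a, b, exact_n_max = 0)$p_value
  expect_lt(abs(pe - pn), 0.01)
})

test_that("post-hoc paired t matches the closed form and orders adjustments", {
  y <- cbind(a = c(10, 12, 9, 11, 13), b = c(11, 14, 9, 12, 15))
  res <- posthoc_pairwise(y)
  d <- y[, 1] - y[, 2]
  t_hand <- mean(d) / (sd(d) / sqrt(5))
  expect_equal(res$statistic[1], t_hand, tolerance = 1e-12)
  expect_equal(res$p[1], 2 * pt(-abs(t_hand), 4), tolerance = 1e-12)

  # identical columns: t = 0, p = 1
  same <- cbind(a = 1:5, b = 1:5)
  expect_equal(posthoc_pairwise(same)$p, 1)

  # Holm-adjusted p never below unadjusted
  set.seed(2)
  y4 <- matrix(rnorm(20), 5, 4, dimnames = list(NULL, letters[1:4]))
  r4 <- posthoc_pairwise(y4)
  expect_true(all(r4$p_holm >= r4$p - 1e-12))
  expect_equal(nrow(r4), 6)

  # Wilcoxon alternative runs
  rw <- posthoc_pairwise(y4, method = "wilcoxon")
  expect_true(all(rw$p >= 0 & rw$p <= 1))
})

test_that("Spearman: sign, exact enumeration oracle, errors", {
  x <- 1:8
  r <- spearman_test(x, rev(x))
  expect_equal(r$statistic, -1)

  set.seed(19)
  for (rep in 1:3) {
    a <- rnorm(7); b <- rnorm(7)
    got <- spearman_test(a, b)
    expect_equal(got$p_value, oracle_spearman_exact(a, b), tolerance = 1e-10)
  }

  expect_error(spearman_test(rep(1, 5), rnorm(5)),
               class = "stresshrv_undefined_correlation")
  expect_error(spearman_test(1:2, 2:1), class = "stresshrv_domain_error")
})

test_that("all tests are invariant to subject ordering", {
  set.seed(55)
  y <- matrix(rnorm(8 * 4), 8, 4)
  ord <- sample(8)
  expect_equal(friedman_test(y)$p_value, friedman_test(y[ord, ])$p_value)
  expect_equal(wilcoxon_signed_rank(y[, 1], y[, 2])$p_value,
               wilcoxon_signed_rank(y[ord, 1], y[ord, 2])$p_value)
  expect_equal(spearman_test(y[, 1], y[, 2])$p_value,
               spearman_test(y[ord, 1], y[ord, 2])$p_value)
})

test_that("zscore standardises, is affine-invariant and invertible", {
  z <- zscore(c(1, 2, 3, 4))
  expect_equal(mean(z), 0)
  expect_equal(sd(z), 1)

  v <- c(3, 9, 1, 7, 5)
  expect_equal(zscore(2.5 * v + 7), zscore(v))

  # round-trip: v = mean + z * sd
  expect_equal(mean(v) + zscore(v) * sd(v), v)

  expect_error(zscore(rep(2, 4)), class = "stresshrv_domain_error")
})
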