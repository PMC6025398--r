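## Nonparametric repeated-measures statistics.
##
## Friedman omnibus across k conditions with exact permutation p for small
## n (dynamic program identical to full (k!)^n enumeration), Wilcoxon
## signed-rank with exact null via generating-polynomial convolution
## (identical to 2^n sign enumeration), paired-t post-hoc comparisons,
## Spearman correlation with exact permutation p for small n, and pooled
## z-scoring of cognitive measures. All exact distributions are verified
## against literal brute-force enumeration in the test suite.

new_test_result <- function(method, statistic, p_value, n, extra = list()) {
  out <- c(list(method = method, statistic = statistic,
                p_value = p_value, n = n), extra)
  class(out) <- "test_result"
  out
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("<%s> statistic = %.4g, p = %.4g, n = %d\n",
              x$method, x$statistic, x$p_value, x$n))
  invisible(x)
}

rank_ties <- function(x) rank(x, ties.method = "average")

friedman_statistic <- function(ranks) {
  n <- nrow(ranks); k <- ncol(ranks)
  cs <- colSums(ranks)
  num <- (k - 1) * sum((cs - n * (k + 1) / 2)^2)
  den <- sum(ranks^2) - n * k * (k + 1)^2 / 4
  if (den <= 0) return(0)   # all rows fully tied
  num / den
}

#' Friedman rank test across repeated conditions
#'
#' Chi-square-distributed rank statistic with average-rank tie handling.
#' For `n <= exact_n_max` subjects and `k <= 4` conditions the permutation
#' p-value is computed exactly: the null permutes each subject's ranks
#' independently, and because the tie term is invariant under within-row
#' permutation the statistic depends only on the column rank sums, whose
#' exact distribution is accumulated row by row (equivalent to enumerating
#' all (k!)^n arrangements).
#'
#' @param y Numeric matrix, subjects x conditions (complete cases), or a
#'   `study_frame` plus `measure`.
#' @param measure Measure column when `y` is a study frame.
#' @param exact_n_max Largest n for which the exact p is computed
#'   (default 8); larger n use the asymptotic chi-square p.
#' @return A `test_result`; `p_value` is the exact permutation p when
#'   available, else asymptotic; both are reported in the result.
#' @export
friedman_test <- function(y, measure = NULL, exact_n_max = 8L) {
  if (inherits(y, "study_frame")) y <- measure_matrix(y, measure)
  y <- as.matrix(y)
  y <- y[stats::complete.cases(y), , drop = FALSE]
  n <- nrow(y); k <- ncol(y)
  if (n < 2L) stop_domain("Friedman test needs at least 2 complete subjects")
  if (k < 3L) stop_domain("Friedman test needs at least 3 conditions")
  ranks <- t(apply(y, 1, rank_ties))
  stat <- friedman_statistic(ranks)
  p_asym <- stats::pchisq(stat, df = k - 1, lower.tail = FALSE)
  p_exact <- NA_real_
  if (n <= exact_n_max && k <= 4L) p_exact <- friedman_exact_p(ranks)
  new_test_result("friedman", stat,
                  if (!is.na(p_exact)) p_exact else p_asym, n,
                  list(k = k, df = k - 1, p_asymptotic = p_asym,
                       p_exact = p_exact))
}

## Exact permutation distribution of the column rank sums. States are
## column-sum vectors (doubled so .5 ties stay integer), keyed as strings.
friedman_exact_p <- function(ranks) {
  n <- nrow(ranks); k <- ncol(ranks)
  perms <- permutations_of(k)
  states <- new.env(parent = emptyenv())
  assign(paste(integer(k), collapse = ","), 1, envir = states)
  for (i in seq_len(n)) {
    r2 <- as.integer(round(2 * ranks[i, ]))
    nxt <- new.env(parent = emptyenv())
    w <- 1 / nrow(perms)
    for (key in ls(states)) {
      base <- as.integer(strsplit(key, ",", fixed = TRUE)[[1]])
      pr <- get(key, envir = states)
      for (j in seq_len(nrow(perms))) {
        ns <- base + r2[perms[j, ]]
        nk <- paste(ns, collapse = ",")
        assign(nk, (if (exists(nk, envir = nxt)) get(nk, envir = nxt) else 0) +
                 pr * w, envir = nxt)
      }
    }
    states <- nxt
  }
  c_mid <- n * (k + 1)    # doubled scale: 2 * n(k+1)/2
  s_obs <- sum((2 * colSums(ranks) - c_mid)^2)
  p <- 0
  for (key in ls(states)) {
    cs2 <- as.integer(strsplit(key, ",", fixed = TRUE)[[1]])
    if (sum((cs2 - c_mid)^2) >= s_obs - 1e-9)
      p <- p + get(key, envir = states)
  }
  min(1, p)
}

## All permutations of 1..k as a matrix: place k at every position around
## each permutation of 1..(k-1).
permutations_of <- function(k) {
  if (k == 1L) return(matrix(1L, 1, 1))
  sub <- permutations_of(k - 1L)
  out <- matrix(0L, nrow(sub) * k, k)
  row <- 1L
  for (pos in seq_len(k)) {
    for (r in seq_len(nrow(sub))) {
      out[row, pos] <- k
      out[row, -pos] <- sub[r, ]
      row <- row + 1L
    }
  }
  out
}

#' Wilcoxon signed-rank test for paired samples
#'
#' Zero differences are dropped (their count is reported). For
#' `n <= exact_n_max` non-zero pairs the null distribution of the
#' positive-rank sum V is computed exactly by convolving the generating
#' polynomial over 2x-ranks (identical to enumerating all 2^n sign
#' assignments, ties included); otherwise a normal approximation with tie
#' correction and continuity correction is used.
#'
#' @param x,y Paired numeric vectors.
#' @param alternative `"two.sided"` (default), `"greater"` (x > y) or
#'   `"less"`.
#' @param exact_n_max Largest n for the exact null (default 25).
#' @return A `test_result` with `statistic` = V (sum of ranks of positive
#'   differences x - y).
#' @export
wilcoxon_signed_rank <- function(x, y,
                                 alternative = c("two.sided", "greater", "less"),
                                 exact_n_max = 25L) {
  alternative <- match.arg(alternative)
  if (length(x) != length(y)) stop_domain("x and y must be paired")
  keep <- stats::complete.cases(x, y)
  d <- (x - y)[keep]
  n_zero <- sum(d == 0)
  d <- d[d != 0]
  n <- length(d)
  if (n < 2L) {
    if (n == 0L) stop_classed("stresshrv_degenerate_test",
                              "all paired differences are zero")
    stop_domain("need at least 2 non-zero paired differences")
  }
  r <- rank_ties(abs(d))
  v <- sum(r[d > 0])
  if (n <= exact_n_max) {
    r2 <- as.integer(round(2 * r))
    dist <- signrank_exact_dist(r2)          # over V2 = 2V in 0..sum(r2)
    v2 <- as.integer(round(2 * v))
    cdf_le <- sum(dist[seq_len(v2 + 1L)])
    cdf_ge <- sum(dist[(v2 + 1L):length(dist)])
    p <- switch(alternative,
                two.sided = min(1, 2 * min(cdf_le, cdf_ge)),
                greater = cdf_ge,
                less = cdf_le)
    method <- "wilcoxon_signed_rank_exact"
  } else {
    mu <- n * (n + 1) / 4
    tie_tab <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    cc <- 0.5
    z_g <- (v - mu - cc) / sqrt(sig2)
    z_l <- (v - mu + cc) / sqrt(sig2)
    p <- switch(alternative,
                two.sided = min(1, 2 * min(stats::pnorm(z_l),
                                           stats::pnorm(z_g, lower.tail = FALSE))),
                greater = stats::pnorm(z_g, lower.tail = FALSE),
                less = stats::pnorm(z_l))
    method <- "wilcoxon_signed_rank_normal"
  }
  new_test_result(method, v, p, n,
                  list(n_zero_dropped = n_zero, alternative = alternative))
}

## Exact pmf of V2 = 2 * (positive-rank sum) over all sign assignments.
## r2: doubled ranks (integers). Returns pmf vector indexed by V2 = 0..sum(r2).
signrank_exact_dist <- function(r2) {
  pmf <- numeric(sum(r2) + 1L)
  pmf[1L] <- 1
  for (ri in r2) {
    shifted <- c(numeric(ri), pmf[seq_len(length(pmf) - ri)])
    pmf <- (pmf + shifted) / 2
  }
  pmf
}

#' Post-hoc pairwise comparisons between time points
#'
#' Paired-samples t-tests per pair (the mixed design of a nonparametric
#' omnibus with parametric post-hocs mirrors common psychophysiology
#' practice); a Wilcoxon signed-rank alternative is available. Unadjusted
#' p-values are the primary output, with Holm and Bonferroni columns
#' alongside.
#'
#' @param y Subjects x conditions matrix or `study_frame` (+ `measure`).
#' @param pairs List of 2-vectors of condition names/indices; default all
#'   pairs.
#' @param measure Measure column for a study frame.
#' @param method `"paired_t"` (default) or `"wilcoxon"`.
#' @return data.frame with one row per pair: `pair`, `statistic`, `n`, `p`,
#'   `p_holm`, `p_bonferroni`.
#' @export
posthoc_pairwise <- function(y, pairs = NULL, measure = NULL,
                             method = c("paired_t", "wilcoxon")) {
  method <- match.arg(method)
  if (inherits(y, "study_frame")) y <- measure_matrix(y, measure)
  y <- as.matrix(y)
  conds <- colnames(y) %||% as.character(seq_len(ncol(y)))
  if (is.null(pairs))
    pairs <- utils::combn(conds, 2, simplify = FALSE)
  rows <- lapply(pairs, function(pr) {
    a <- y[, pr[1]]; b <- y[, pr[2]]
    keep <- stats::complete.cases(a, b)
    a <- a[keep]; b <- b[keep]
    n <- length(a)
    if (n < 2L) stop_domain("need >= 2 complete pairs per comparison")
    if (method == "paired_t") {
      d <- a - b
      sd_d <- stats::sd(d)
      if (sd_d == 0 && mean(d) != 0)
        stop_classed("stresshrv_degenerate_test",
                     "zero-variance non-zero differences in paired t")
      if (sd_d == 0) return(data.frame(pair = paste(pr, collapse = "-"),
                                       statistic = 0, n = n, p = 1))
      tt <- mean(d) / (sd_d / sqrt(n))
      data.frame(pair = paste(pr, collapse = "-"), statistic = tt, n = n,
                 p = 2 * stats::pt(-abs(tt), df = n - 1))
    } else {
      res <- wilcoxon_signed_rank(a, b)
      data.frame(pair = paste(pr, collapse = "-"), statistic = res$statistic,
                 n = res$n, p = res$p_value)
    }
  })
  out <- do.call(rbind, rows)
  out$p_holm <- stats::p.adjust(out$p, "holm")
  out$p_bonferroni <- stats::p.adjust(out$p, "bonferroni")
  out
}

#' Spearman rank correlation
#'
#' Average-rank ties. For `n <= exact_n_max` without exceeding feasibility
#' the two-sided permutation p is exact (all n! permutations of one rank
#' vector); larger n use the t approximation
#' `t = rho * sqrt((n-2)/(1-rho^2))`.
#'
#' @param x,y Numeric vectors, n >= 3, neither constant.
#' @param exact_n_max Largest n for exact enumeration (default 8).
#' @return A `test_result` with `statistic` = rho.
#' @export
spearman_test <- function(x, y, exact_n_max = 8L) {
  keep <- stats::complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3L) stop_domain("Spearman correlation needs n >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop_classed("stresshrv_undefined_correlation",
                 "constant input: correlation undefined")
  rx <- rank_ties(x); ry <- rank_ties(y)
  rho <- stats::cor(rx, ry)
  if (n <= exact_n_max) {
    perms <- permutations_of(n)
    rho_perm <- apply(perms, 1, function(idx) stats::cor(rx, ry[idx]))
    p <- mean(abs(rho_perm) >= abs(rho) - 1e-12)
    method <- "spearman_exact"
  } else {
    tt <- rho * sqrt((n - 2) / max(1e-300, 1 - rho^2))
    p <- 2 * stats::pt(-abs(tt), df = n - 2)
    method <- "spearman_t_approx"
  }
  new_test_result(method, rho, p, n)
}

#' Z-score standardisation
#'
#' Centres and scales by the mean and (sample) standard deviation of the
#' pooled vector, as used for cognitive-performance measures pooled across
#' the pre- and post-stress task sessions.
#'
#' @param values Numeric vector, n >= 2 with nonzero spread.
#' @return Standardised vector (mean 0, sd 1).
#' @export
zscore <- function(values) {
  v <- values[!is.na(values)]
  if (length(v) < 2L) stop_domain("z-scoring needs n >= 2")
  s <- stats::sd(v)
  if (s == 0) stop_domain("z-scoring needs nonzero spread")
  (values - mean(v)) / s
}
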