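# Independent oracles and small fixture builders shared across tests.
# Oracles are deliberately naive (literal enumeration, two-pass formulas)
# and never call the implementation paths they check.

# Match detected beats to true beats within tol seconds (greedy 1-1).
match_beats <- function(detected, truth, tol = 0.05) {
  used <- logical(length(detected))
  hits <- 0L
  for (t in truth) {
    d <- abs(detected - t)
    d[used] <- Inf
    j <- which.min(d)
    if (length(j) && d[j] <= tol) { used[j] <- TRUE; hits <- hits + 1L }
  }
  list(sensitivity = hits / length(truth),
       ppv = sum(used) / length(detected))
}

# Literal forward-pass application of the published RR validity rules.
oracle_filter_rr <- function(iv, abs_low = 300, abs_high = 3000,
                             max_delta = 400, max_rel = 0.25, win = 5) {
  valid <- logical(length(iv))
  hist <- numeric(0)
  for (i in seq_along(iv)) {
    x <- iv[i]
    ok <- x >= abs_low && x <= abs_high
    if (ok && length(hist) >= 1 && abs(x - hist[length(hist)]) > max_delta)
      ok <- FALSE
    if (ok && length(hist) >= win) {
      m <- mean(tail(hist, win))
      if (abs(x - m) > max_rel * m) ok <- FALSE
    }
    valid[i] <- ok
    if (ok) hist <- c(hist, x)
  }
  valid
}

# Two-pass standard deviation (population form).
oracle_sd_pop <- function(x) sqrt(sum((x - sum(x) / length(x))^2) / length(x))

# Brute-force exact Friedman permutation p over all (k!)^n arrangements.
oracle_friedman_exact <- function(y) {
  n <- nrow(y); k <- ncol(y)
  ranks <- t(apply(y, 1, rank))
  stat_of <- function(r) {
    cs <- colSums(r)
    num <- (k - 1) * sum((cs - n * (k + 1) / 2)^2)
    den <- sum(r^2) - n * k * (k + 1)^2 / 4
    if (den <= 0) 0 else num / den
  }
  s_obs <- stat_of(ranks)
  perms <- asplit(perm_matrix(k), 1)
  combos <- expand.grid(rep(list(seq_along(perms)), n))
  cnt <- 0L
  for (ci in seq_len(nrow(combos))) {
    r <- ranks
    for (i in seq_len(n)) r[i, ] <- ranks[i, perms[[combos[ci, i]]]]
    if (stat_of(r) >= s_obs - 1e-9) cnt <- cnt + 1L
  }
  cnt / nrow(combos)
}

# All permutations of 1..k, independent of the package implementation.
perm_matrix <- function(k) {
  if (k == 1) return(matrix(1, 1, 1))
  sub <- perm_matrix(k - 1)
  do.call(rbind, lapply(seq_len(k), function(pos) {
    cbind_pos <- matrix(0, nrow(sub), k)
    cbind_pos[, pos] <- k
    cbind_pos[, -pos] <- sub
    cbind_pos
  }))
}

# Brute-force exact Wilcoxon signed-rank p (two-sided) over 2^n signs.
oracle_wilcoxon_exact <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- signs %*% r
  p_le <- mean(v_all <= v_obs + 1e-9)
  p_ge <- mean(v_all >= v_obs - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}

# Brute-force exact two-sided Spearman permutation p over all n! orders.
oracle_spearman_exact <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  rho_obs <- cor(rx, ry)
  perms <- perm_matrix(length(x))
  rho_all <- apply(perms, 1, function(idx) cor(rx, ry[idx]))
  mean(abs(rho_all) >= abs(rho_obs) - 1e-12)
}

# Small deterministic CRTT log builder.
make_crtt_log <- function(stimulus, response_key, rt_ms = NULL) {
  n <- length(stimulus)
  if (is.null(rt_ms)) rt_ms <- ifelse(is.na(response_key), NA_real_, 500)
  df <- data.frame(trial = seq_len(n), stimulus = stimulus,
                   onset_s = seq_len(n) * 5, display_ms = 300,
                   response_key = response_key, rt_ms = rt_ms,
                   outcome = classify_response(stimulus, response_key),
                   stringsAsFactors = FALSE)
  class(df) <- c("crtt_log", "data.frame")
  df
}
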