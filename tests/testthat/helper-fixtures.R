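# Shared fixtures and independent oracles, all built in code.

toy_mapping <- function() {
  fv_mapping(
    item = c("carrot", "pumpkin", "spinach", "kale", "tomato", "mushroom",
             "mango", "papaya", "orange", "tangerine", "banana", "apple"),
    group = rep(fv_groups(), each = 2),
    sentinel = rep(c(TRUE, FALSE), times = 6)
  )
}

# one recall record per mapped item name given per-item grams
toy_recall <- function(items, grams, respondent_id = "r1", day = 1) {
  tibble::tibble(respondent_id = respondent_id, day = day,
                 item = items, grams = grams)
}

# random matched 0/1 indicator streams for one group
random_indicator_pair <- function(n, p_dqq = 0.5, p_r24h = 0.5) {
  ids <- sprintf("id%04d", seq_len(n))
  base <- tibble::tibble(respondent_id = ids, day = 1L)
  for (g in fv_groups()) {
    base[[g]] <- 0L
  }
  dqq <- base
  rec <- base
  dqq$va_veg <- stats::rbinom(n, 1, p_dqq)
  rec$va_veg <- stats::rbinom(n, 1, p_r24h)
  list(dqq = dqq, r24h = rec)
}

# brute-force per-observation tabulation oracle for agreement statistics
oracle_agreement <- function(dqq_flags, recall_flags) {
  stopifnot(length(dqq_flags) == length(recall_flags))
  a <- b <- c <- d <- 0
  for (i in seq_along(dqq_flags)) {
    q <- dqq_flags[i]; r <- recall_flags[i]
    if (q == 0 && r == 0) a <- a + 1
    else if (q == 1 && r == 0) b <- b + 1
    else if (q == 0 && r == 1) c <- c + 1
    else d <- d + 1
  }
  n <- a + b + c + d
  list(
    a = a, b = b, c = c, d = d, n = n,
    agreement_pct = (a + d) / n * 100,
    fp_pct = b / n * 100, fn_pct = c / n * 100,
    sensitivity = if (c + d > 0) d / (c + d) else NA_real_,
    specificity = if (a + b > 0) a / (a + b) else NA_real_
  )
}

# draw n rows from a trivariate normal with unit variances and the given
# correlations (r12 = cor(v1,v2), r13 = cor(v1,v3), r23 = cor(v2,v3))
rtrivariate <- function(n, r12, r13, r23) {
  S <- matrix(c(1, r12, r13, r12, 1, r23, r13, r23, 1), 3, 3)
  z <- matrix(stats::rnorm(3 * n), n, 3)
  z %*% chol(S)
}

# sign-flip permutation oracle for the paired Wilcoxon test (two-sided)
oracle_wilcoxon_perm <- function(x, y, n_perm = 10000) {
  d <- x - y
  d <- d[d != 0]
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  mu <- sum(r) / 2
  signs <- matrix(stats::runif(n_perm * length(d)) < 0.5, n_perm, length(d))
  v_perm <- signs %*% r
  mean(abs(v_perm - mu) >= abs(v_obs - mu) - 1e-12)
}
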