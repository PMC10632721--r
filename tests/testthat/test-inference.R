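test_that("paired Wilcoxon handles identity, shift and matches a permutation oracle", {
  s <- c(2L, 3L, 1L, 4L, 0L, 5L)
  w <- wilcoxon_paired(s, s)
  expect_equal(w$p_value, 1)
  expect_equal(w$statistic, 0)
  expect_equal(w$median_diff, 0)

  # constant +1 shift over 50 pairs: maximal one-sided evidence
  set.seed(3)
  y <- sample(0:5, 50, replace = TRUE)
  w <- wilcoxon_paired(y + 1L, y)
  expect_lt(w$p_value, 0.05)
  expect_equal(w$median_diff, 1)

  # random paired scores: normal-approximation p agrees with a
  # sign-flip permutation null
  set.seed(15)
  x <- sample(0:6, 200, replace = TRUE)
  y <- sample(0:6, 200, replace = TRUE, prob = c(3, 3, 2, 2, 2, 1, 1))
  w <- wilcoxon_paired(x, y)
  p_perm <- oracle_wilcoxon_perm(x, y, n_perm = 10000)
  expect_lt(abs(w$p_value - p_perm), 0.02)
})

test_that("Wilcoxon p-values are approximately uniform under the paired null", {
  set.seed(77)
  p <- replicate(300, {
    x <- rnorm(50); y <- rnorm(50)
    wilcoxon_paired(x, y)$p_value
  })
  ks <- suppressWarnings(stats::ks.test(p, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("standardized mixed-model slope: exact, OLS-limit and recovery behaviour", {
  set.seed(5)
  # perfect relation: slope 1 with a collapsed interval
  x <- rnorm(40); id <- rep(1:20, each = 2)
  f <- mixed_beta_st(x, x, id)
  expect_equal(f$beta_st, 1)
  expect_equal(c(f$ci_low, f$ci_high), c(1, 1))

  # one observation per respondent: equals the standardized OLS slope
  x <- rnorm(150); y <- 0.5 * x + rnorm(150)
  f <- mixed_beta_st(x, y, seq_along(x))
  ols <- lm(scale(y) ~ scale(x))
  expect_equal(f$beta_st, unname(coef(ols)[2]), tolerance = 1e-6)
  expect_equal(f$sigma_u, 0)

  # clustered data with known standardized slope 0.4 is recovered
  set.seed(6)
  n_resp <- 300
  id <- rep(seq_len(n_resp), each = 2)
  u <- rnorm(n_resp, 0, sqrt(0.3))[id]
  xs <- rnorm(2 * n_resp)
  ys <- 0.4 * xs + u + rnorm(2 * n_resp, 0, sqrt(0.54))
  f <- mixed_beta_st(xs, ys, id)
  expect_equal(f$beta_st, 0.4, tolerance = 0.1)
  expect_true(f$ci_low <= f$beta_st && f$beta_st <= f$ci_high)
  expect_gt(f$sigma_u, 0.2)

  # degenerate inputs are refused
  expect_error(mixed_beta_st(rep(1, 10), rnorm(10), rep(1:5, 2)),
               "variance")
})

test_that("dependent-correlation comparison: symmetry, antisymmetry and guards", {
  # equal correlations: no evidence, interval symmetric about 0
  cmp <- compare_dependent_correlations(0.5, 0.5, 0.8, 100)
  expect_equal(cmp$z, 0)
  expect_equal(cmp$p_value, 1)
  expect_equal(cmp$zou_low, -cmp$zou_high)

  # swapping the two correlations negates z and reflects the interval
  a <- compare_dependent_correlations(0.6, 0.4, 0.7, 500)
  b <- compare_dependent_correlations(0.4, 0.6, 0.7, 500)
  expect_equal(a$z, -b$z)
  expect_equal(a$zou_low, -b$zou_high)
  expect_equal(a$zou_high, -b$zou_low)
  expect_true(a$zou_low <= a$diff && a$diff <= a$zou_high)

  expect_error(compare_dependent_correlations(1, 0.4, 0.5, 100), "Fisher")
  expect_error(compare_dependent_correlations(0.9, -0.9, 0.9, 100),
               "semi-definite")
  expect_error(compare_dependent_correlations(0.5, 0.4, 0.6, 5), "10")
})

test_that("Zou interval agrees with a nonparametric bootstrap on sampled data", {
  set.seed(21)
  v <- rtrivariate(500, 0.6, 0.4, 0.7)
  t <- correlation_triple(v[, 1], v[, 2], v[, 3])
  cmp <- compare_dependent_correlations(t)

  boot <- replicate(2000, {
    i <- sample.int(500, replace = TRUE)
    cor(v[i, 1], v[i, 2]) - cor(v[i, 1], v[i, 3])
  })
  ci <- unname(stats::quantile(boot, c(0.025, 0.975)))
  expect_equal(cmp$zou_low, ci[1], tolerance = 0.05)
  expect_equal(cmp$zou_high, ci[2], tolerance = 0.05)
  # and the z test agrees with the bootstrap about sign and significance
  expect_gt(cmp$z, 0)
  expect_lt(cmp$p_value, 0.05)
  expect_gt(ci[1], 0)
})

test_that("cut-off analysis finds the separating threshold and matches enumeration", {
  # perfectly separable: adherent observations score >= 4, others <= 2
  set.seed(31)
  lab <- rbinom(300, 1, 0.4) == 1
  score <- ifelse(lab, sample(4:6, 300, replace = TRUE),
                  sample(0:2, 300, replace = TRUE))
  intake <- ifelse(lab, runif(300, 420, 800), runif(300, 50, 380))
  res <- cutoff_analysis(score, score, intake)
  opt <- res$optimum[res$optimum$method == "dqq", ]
  expect_equal(opt$youden_j, 1)
  expect_gt(opt$cutoff, 2)
  expect_lt(opt$cutoff, 4)

  # labels independent of score: J near zero
  score2 <- sample(0:6, 300, replace = TRUE)
  res2 <- cutoff_analysis(score2, score2, intake)
  expect_lt(max(res2$sweep$youden_j), 0.25)

  # exhaustive oracle: recompute J at every half-integer cut-off by loop
  score3 <- sample(0:6, 500, replace = TRUE, prob = c(1, 2, 3, 4, 3, 2, 1))
  intake3 <- 50 + 120 * score3 + rnorm(500, 0, 150)
  intake3 <- pmax(intake3, 0)
  res3 <- cutoff_analysis(score3, score3, intake3)
  lab3 <- intake3 >= 400
  best_j <- -Inf; best_k <- NA
  for (k in seq(-0.5, 6.5, by = 1)) {
    sens <- mean(score3[lab3] >= k)
    spec <- mean(score3[!lab3] < k)
    j <- sens + spec - 1
    if (j > best_j + 1e-12) { best_j <- j; best_k <- k }
  }
  opt3 <- res3$optimum[res3$optimum$method == "dqq", ]
  expect_equal(opt3$youden_j, best_j)
  expect_equal(opt3$cutoff, best_k)

  expect_error(cutoff_analysis(score3, score3, rep(500, 500)), "one side")
})

test_that("proportion above an integer cut-off is reported per method", {
  res <- cutoff_analysis(
    score_dqq = c(0, 1, 3, 4, 5, 6), score_r24h = c(0, 0, 1, 3, 3, 4),
    intake_g = c(100, 200, 300, 450, 500, 700), who_grams = 400, cutoff = 3
  )
  expect_equal(res$prop_above$prop_pct[res$prop_above$method == "dqq"],
               4 / 6 * 100)
  expect_equal(res$prop_above$prop_pct[res$prop_above$method == "r24h"],
               3 / 6 * 100)
})
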