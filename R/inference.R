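#' Paired Wilcoxon signed-rank test on matched scores
#'
#' Tests whether the questionnaire-derived and recall-derived scores differ
#' systematically, using the signed-rank test on the per-observation
#' differences. Zero differences are discarded per the standard procedure;
#' p-values use the tie-corrected normal approximation (scores are small
#' integers, so ties are ubiquitous and an exact distribution unavailable).
#' When every difference is zero the test is vacuous: statistic 0, p = 1.
#'
#' @param x,y Matched numeric vectors (e.g. questionnaire and recall
#'   scores for the same respondent-days).
#' @return List with `statistic` (V, the positive-rank sum), `p_value`,
#'   `median_diff` (median of `x - y`) and `n_nonzero`.
#' @export
wilcoxon_paired <- function(x, y) {
  if (length(x) != length(y)) abort("`x` and `y` must have equal length.")
  if (length(x) < 1) abort("At least one matched pair is required.")
  d <- x - y
  if (all(d == 0)) {
    return(list(statistic = 0, p_value = 1, median_diff = 0, n_nonzero = 0L))
  }
  ht <- suppressWarnings(
    wilcox.test(x, y, paired = TRUE, exact = FALSE, correct = TRUE)
  )
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       median_diff = median(d), n_nonzero = sum(d != 0))
}

#' Standardized slope from a random-intercept linear mixed model
#'
#' Fits `y* ~ beta * x* + u_respondent + e` by REML, where `x*` and `y*`
#' are z-standardized over all observations, and returns the standardized
#' slope with a 95% Wald interval. With repeated observations per
#' respondent the random intercept `u` absorbs within-person correlation;
#' the standardized slope then plays the role of a correlation-like effect
#' size for clustered data.
#'
#' When every respondent contributes exactly one observation the random
#' intercept is unidentifiable; the fit then reduces to ordinary least
#' squares on the standardized variables (the `sigma_u = 0` limit), which
#' is what this function computes in that case.
#'
#' @param x,y Numeric vectors (predictor and outcome), one value per
#'   observation; both must have positive variance.
#' @param respondent_id Vector of respondent identifiers, same length.
#' @param conf_level Confidence level for the Wald interval.
#' @return Object of class `fv_lmm`: list with `beta_st`, `ci_low`,
#'   `ci_high`, `sigma_u`, `sigma_e`, `n_obs`, `n_respondents`.
#' @export
mixed_beta_st <- function(x, y, respondent_id, conf_level = 0.95) {
  n <- length(x)
  if (length(y) != n || length(respondent_id) != n) {
    abort("`x`, `y` and `respondent_id` must have equal length.")
  }
  if (n < 3) abort("At least 3 observations are required.")
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    abort("`x` and `y` must be finite.")
  }
  id <- factor(respondent_id)
  if (nlevels(id) < 2) abort("At least two respondents are required.")
  if (sd(x) == 0 || sd(y) == 0) {
    abort("Zero variance in `x` or `y`; the standardized slope is undefined.")
  }

  zc <- qnorm(1 - (1 - conf_level) / 2)
  d <- tibble(
    xs = (x - mean(x)) / sd(x),
    ys = (y - mean(y)) / sd(y),
    id = id
  )

  # perfect linear relation: slope is +-1 with no residual variance, and
  # the mixed model's variance components are degenerate
  r <- cor(d$xs, d$ys)
  if (abs(r) >= 1 - 1e-12) {
    b <- sign(r)
    return(structure(
      list(beta_st = b, ci_low = b, ci_high = b, sigma_u = 0, sigma_e = 0,
           n_obs = n, n_respondents = nlevels(id)),
      class = "fv_lmm"
    ))
  }

  if (nlevels(id) == n) {
    # one observation per respondent: random intercept unidentifiable,
    # model reduces to standardized OLS
    fit <- lm(ys ~ xs, data = d)
    beta <- unname(coef(fit)[["xs"]])
    se <- sqrt(vcov(fit)["xs", "xs"])
    return(structure(
      list(beta_st = beta, ci_low = beta - zc * se, ci_high = beta + zc * se,
           sigma_u = 0, sigma_e = summary(fit)$sigma,
           n_obs = n, n_respondents = nlevels(id)),
      class = "fv_lmm"
    ))
  }

  fit <- tryCatch(
    suppressMessages(lme4::lmer(ys ~ xs + (1 | id), data = d, REML = TRUE)),
    error = function(e) {
      abort(sprintf("Mixed model failed to fit: %s", conditionMessage(e)))
    }
  )
  beta <- unname(lme4::fixef(fit)[["xs"]])
  se <- sqrt(as.matrix(vcov(fit))["xs", "xs"])
  vc <- as.data.frame(lme4::VarCorr(fit))
  sigma_u <- vc$sdcor[vc$grp == "id"]
  sigma_e <- vc$sdcor[vc$grp == "Residual"]
  structure(
    list(beta_st = beta, ci_low = beta - zc * se, ci_high = beta + zc * se,
         sigma_u = sigma_u, sigma_e = sigma_e,
         n_obs = n, n_respondents = nlevels(id)),
    class = "fv_lmm"
  )
}

#' @export
print.fv_lmm <- function(x, ...) {
  cat(sprintf(
    "Standardized mixed-model slope: beta_st = %.3f (95%% CI %.3f, %.3f)\n",
    x$beta_st, x$ci_low, x$ci_high
  ))
  cat(sprintf("  sigma_u = %.3f, sigma_e = %.3f, %d obs / %d respondents\n",
              x$sigma_u, x$sigma_e, x$n_obs, x$n_respondents))
  invisible(x)
}

#' Correlations of intake with the two method scores
#'
#' Plain product-moment correlations over all observations (clustering
#' ignored): `r12` between gram intake and the recall-derived score, `r13`
#' between intake and the questionnaire-derived score, and `r23` between
#' the two scores. These feed [compare_dependent_correlations()], whose
#' reference distribution assumes independent observations; the
#' cluster-respecting counterpart is [mixed_beta_st()], and both are
#' reported side by side by [run_validation()].
#'
#' @param intake Gram intake per observation.
#' @param score_r24h,score_dqq Matched scores from the two methods.
#' @return Object of class `fv_cor_triple`: list `r12`, `r13`, `r23`, `n`.
#' @export
correlation_triple <- function(intake, score_r24h, score_dqq) {
  if (length(intake) != length(score_r24h) ||
      length(intake) != length(score_dqq)) {
    abort("All three vectors must have equal length.")
  }
  ok <- complete.cases(intake, score_r24h, score_dqq)
  intake <- intake[ok]; score_r24h <- score_r24h[ok]; score_dqq <- score_dqq[ok]
  structure(
    list(r12 = cor(intake, score_r24h),
         r13 = cor(intake, score_dqq),
         r23 = cor(score_r24h, score_dqq),
         n = length(intake)),
    class = "fv_cor_triple"
  )
}

#' Compare two dependent correlations sharing one variable
#'
#' Both correlations involve the same intake variable (variable 1), so they
#' are dependent "overlapping" correlations. Two complementary procedures
#' are computed:
#' \describe{
#'   \item{Hittner z}{the difference of the Fisher-transformed correlations
#'     scaled by their joint standard error, with the covariance term
#'     evaluated at the mean of `r12` and `r13`; two-sided p from the
#'     standard normal.}
#'   \item{Zou interval}{a confidence interval for `r12 - r13` assembled
#'     from the individual Fisher-interval limits of the two correlations
#'     and the estimated correlation between the two sample correlations.}
#' }
#'
#' @param r12 Correlation of variable 1 with variable 2, or an
#'   [correlation_triple()] object (in which case the remaining arguments
#'   are taken from it).
#' @param r13 Correlation of variable 1 with variable 3.
#' @param r23 Correlation of variables 2 and 3.
#' @param n Number of observations.
#' @param conf_level Confidence level for the Zou interval.
#' @return Object of class `fv_cor_cmp`: list with `z`, `p_value`,
#'   `zou_low`, `zou_high`, `diff` (= r12 - r13), `conf_level`, `n`.
#' @export
compare_dependent_correlations <- function(r12, r13 = NULL, r23 = NULL,
                                           n = NULL, conf_level = 0.95) {
  if (inherits(r12, "fv_cor_triple") || (is.list(r12) && is.null(r13))) {
    t <- r12
    r12 <- t$r12; r13 <- t$r13; r23 <- t$r23; n <- t$n
  }
  if (n < 10) abort("At least 10 observations are required.")
  if (abs(r12) >= 1 || abs(r13) >= 1) {
    abort("|r12| and |r13| must be < 1 (Fisher transform undefined at 1).")
  }
  cm <- matrix(c(1, r12, r13, r12, 1, r23, r13, r23, 1), 3, 3)
  if (min(eigen(cm, symmetric = TRUE, only.values = TRUE)$values) < -1e-8) {
    abort("(r12, r13, r23) do not form a positive semi-definite correlation matrix.")
  }

  z12 <- atanh(r12); z13 <- atanh(r13)

  # Hittner z: covariance of the two Fisher z's evaluated at the mean r
  if (z12 == z13) {
    z <- 0
  } else {
    rbar2 <- ((r12 + r13) / 2)^2
    cv <- (r23 * (1 - 2 * rbar2) - 0.5 * rbar2 * (1 - 2 * rbar2 - r23^2)) /
      (1 - rbar2)^2
    z <- (z12 - z13) * sqrt((n - 3) / (2 - 2 * cv))
  }
  p <- 2 * pnorm(-abs(z))

  # Zou interval for r12 - r13
  zc <- qnorm(1 - (1 - conf_level) / 2)
  se <- 1 / sqrt(n - 3)
  l1 <- tanh(z12 - zc * se); u1 <- tanh(z12 + zc * se)
  l2 <- tanh(z13 - zc * se); u2 <- tanh(z13 + zc * se)
  corr12_13 <- ((r23 - r12 * r13 / 2) * (1 - r12^2 - r13^2 - r23^2) + r23^3) /
    ((1 - r12^2) * (1 - r13^2))
  diff <- r12 - r13
  zou_low <- diff - sqrt((r12 - l1)^2 + (u2 - r13)^2 -
                           2 * corr12_13 * (r12 - l1) * (u2 - r13))
  zou_high <- diff + sqrt((u1 - r12)^2 + (r13 - l2)^2 -
                            2 * corr12_13 * (u1 - r12) * (r13 - l2))

  structure(
    list(z = z, p_value = p, zou_low = zou_low, zou_high = zou_high,
         diff = diff, conf_level = conf_level, n = n),
    class = "fv_cor_cmp"
  )
}

#' @export
print.fv_cor_cmp <- function(x, ...) {
  cat(sprintf(
    "Dependent overlapping correlations: r12 - r13 = %.3f\n  Hittner z = %.3f (p = %.4g); Zou %d%% CI (%.3f, %.3f)\n",
    x$diff, x$z, x$p_value, round(100 * x$conf_level), x$zou_low, x$zou_high
  ))
  invisible(x)
}

#' Score cut-off analysis against a gram-intake adherence threshold
#'
#' Labels observations by whether total fruit and vegetable intake reaches
#' `who_grams` (default 400 g/d, the WHO recommendation) and sweeps
#' half-integer cut-offs -0.5, 0.5, ..., 6.5 of each method's score,
#' recording sensitivity, specificity and Youden's J
#' (sensitivity + specificity - 1) for classifying adherence. The optimum
#' per method is the cut-off maximizing J (lowest cut-off on ties). Also
#' reports, for the supplied integer `cutoff`, the percentage of
#' observations scoring at or above it per method.
#'
#' @param score_dqq,score_r24h Matched integer scores from the two methods.
#' @param intake_g Matched total gram intake per observation.
#' @param who_grams Adherence threshold in grams/day.
#' @param cutoff Integer cut-off for the proportion-above summary.
#' @return Object of class `fv_cutoff`: list with `sweep` (per method and
#'   cut-off: sensitivity, specificity, `youden_j`), `optimum` (per
#'   method), `prop_above` (per method, percent), `who_grams`, `cutoff`.
#' @export
cutoff_analysis <- function(score_dqq, score_r24h, intake_g,
                            who_grams = 400, cutoff = 3) {
  n <- length(intake_g)
  if (length(score_dqq) != n || length(score_r24h) != n) {
    abort("Scores and intake must have equal length.")
  }
  label <- intake_g >= who_grams
  if (all(label) || !any(label)) {
    abort(sprintf(
      "All observations fall on one side of %g g/d; cut-off analysis undefined.",
      who_grams
    ))
  }

  cuts <- seq(-0.5, 6.5, by = 1)
  sweep_one <- function(score, method) {
    rows <- lapply(cuts, function(k) {
      pos <- score >= k
      tibble(
        method = method, cutoff = k,
        sensitivity = mean(pos[label]),
        specificity = mean(!pos[!label])
      )
    })
    bind_rows(rows) |> mutate(youden_j = .data$sensitivity + .data$specificity - 1)
  }
  sweep <- bind_rows(sweep_one(score_dqq, "dqq"), sweep_one(score_r24h, "r24h"))
  optimum <- sweep |>
    group_by(.data$method) |>
    arrange(desc(.data$youden_j), .data$cutoff, .by_group = TRUE) |>
    slice(1) |>
    ungroup()
  prop_above <- tibble(
    method = c("dqq", "r24h"), cutoff = cutoff,
    prop_pct = c(mean(score_dqq >= cutoff), mean(score_r24h >= cutoff)) * 100
  )
  structure(
    list(sweep = sweep, optimum = optimum, prop_above = prop_above,
         who_grams = who_grams, cutoff = cutoff),
    class = "fv_cutoff"
  )
}

#' @export
print.fv_cutoff <- function(x, ...) {
  cat(sprintf("Cut-off analysis against intake >= %g g/d\n", x$who_grams))
  for (i in seq_len(nrow(x$optimum))) {
    cat(sprintf("  %s: optimal cut-off %.1f (Youden J = %.3f)\n",
                x$optimum$method[i], x$optimum$cutoff[i],
                x$optimum$youden_j[i]))
  }
  for (i in seq_len(nrow(x$prop_above))) {
    cat(sprintf("  %% scoring >= %d (%s): %.1f\n",
                x$cutoff, x$prop_above$method[i], x$prop_above$prop_pct[i]))
  }
  invisible(x)
}
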