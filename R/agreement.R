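#' Two-by-two method cross-tabulation for one food group
#'
#' Cross-tabulates the questionnaire (DQQ) and recall (24hR) indicators of
#' one food group over matched respondent-days. Cells follow the convention
#' used throughout the package:
#' \describe{
#'   \item{a}{neither method reports consumption,}
#'   \item{b}{questionnaire yes, recall no (false positive, type I),}
#'   \item{c}{questionnaire no, recall yes (false negative, type II),}
#'   \item{d}{both report consumption.}
#' }
#' The recall is the reference method in all asymmetric statistics.
#' Observations present in only one method are dropped (their count is kept
#' in the `n_dropped` field).
#'
#' @param dqq_ind,recall_ind Indicator tables from [dqq_indicators()] and
#'   [recall_indicators()], matched on (`respondent_id`, `day`).
#' @param group A food-group code (see [fv_groups()]).
#' @return An object of class `fv_2x2`: list with fields `a`, `b`, `c`,
#'   `d`, `n`, `group`, `n_dropped`.
#' @export
crosstab <- function(dqq_ind, recall_ind, group) {
  group <- check_group(group)
  keys <- c("respondent_id", "day")
  m <- inner_join(
    dqq_ind[, c(keys, group)] |> rename(dqq = all_of(group)),
    recall_ind[, c(keys, group)] |> rename(r24h = all_of(group)),
    by = keys
  )
  if (nrow(m) == 0) abort("No respondent-days matched across the two methods.")
  n_dropped <- (nrow(dqq_ind) - nrow(m)) + (nrow(recall_ind) - nrow(m))
  two_by_two(
    a = sum(m$dqq == 0 & m$r24h == 0),
    b = sum(m$dqq == 1 & m$r24h == 0),
    c = sum(m$dqq == 0 & m$r24h == 1),
    d = sum(m$dqq == 1 & m$r24h == 1),
    group = group, n_dropped = n_dropped
  )
}

#' @rdname crosstab
#' @param a,b,c,d Non-negative cell counts.
#' @param n_dropped Count of unmatched observations, for logging.
#' @export
two_by_two <- function(a, b, c, d, group = NA_character_, n_dropped = 0L) {
  counts <- c(a = a, b = b, c = c, d = d)
  if (any(counts < 0) || anyNA(counts)) abort("Cell counts must be non-negative.")
  structure(
    list(a = as.integer(a), b = as.integer(b), c = as.integer(c),
         d = as.integer(d), n = as.integer(a + b + c + d),
         group = group, n_dropped = as.integer(n_dropped)),
    class = "fv_2x2"
  )
}

#' @export
print.fv_2x2 <- function(x, ...) {
  cat(sprintf("2x2 method agreement table%s (n = %d)\n",
              if (is.na(x$group)) "" else paste0(" for ", x$group), x$n))
  cat(sprintf("  a (both no) = %d   b (DQQ only) = %d\n", x$a, x$b))
  cat(sprintf("  c (24hR only) = %d d (both yes) = %d\n", x$c, x$d))
  invisible(x)
}

#' Percentage agreement coefficient
#'
#' `((a + d) / n) * 100`: the percentage of matched respondent-days on
#' which the two methods agree about consumption of a food group.
#'
#' @param t An `fv_2x2` table.
#' @return Agreement in percent.
#' @export
agreement_coefficient <- function(t) {
  stopifnot(inherits(t, "fv_2x2"))
  if (t$n == 0) abort("Agreement undefined for an empty table (n = 0).")
  (t$a + t$d) / t$n * 100
}

#' Sensitivity and specificity of the questionnaire against the recall
#'
#' Treating the recall-derived indicator as the reference: sensitivity is
#' the true-positive rate `d / (c + d)`, specificity the true-negative rate
#' `a / (a + b)`. A rate whose denominator is zero is undefined and
#' reported as `NA` rather than fabricated.
#'
#' @param t An `fv_2x2` table.
#' @return Named numeric vector `c(sensitivity, specificity)`.
#' @export
sensitivity_specificity <- function(t) {
  stopifnot(inherits(t, "fv_2x2"))
  if (t$n == 0) abort("Undefined for an empty table (n = 0).")
  sens <- if (t$c + t$d > 0) t$d / (t$c + t$d) else NA_real_
  spec <- if (t$a + t$b > 0) t$a / (t$a + t$b) else NA_real_
  c(sensitivity = sens, specificity = spec)
}

#' Type I and type II misreporting rates
#'
#' False-positive (type I: questionnaire yes, recall no) and false-negative
#' (type II: questionnaire no, recall yes) percentages, computed over *all*
#' matched observations (`b/n`, `c/n`), so that
#' `agreement + FP + FN = 100` exactly.
#'
#' @param t An `fv_2x2` table.
#' @return Named numeric vector `c(fp_pct, fn_pct)`.
#' @export
misreport_rates <- function(t) {
  stopifnot(inherits(t, "fv_2x2"))
  if (t$n == 0) abort("Undefined for an empty table (n = 0).")
  c(fp_pct = t$b / t$n * 100, fn_pct = t$c / t$n * 100)
}

#' @rdname misreport_rates
#' @return `agreement_stats()`: one-row tibble with `agreement_pct`,
#'   `fp_pct`, `fn_pct`, `sensitivity`, `specificity`.
#' @export
agreement_stats <- function(t) {
  ss <- sensitivity_specificity(t)
  mr <- misreport_rates(t)
  tibble(
    agreement_pct = agreement_coefficient(t),
    fp_pct = mr[["fp_pct"]], fn_pct = mr[["fn_pct"]],
    sensitivity = ss[["sensitivity"]], specificity = ss[["specificity"]]
  )
}

#' Is a prevalence difference meaningful?
#'
#' A between-method difference in food-group consumption prevalence is
#' called meaningful when it is both statistically significant at `alpha`
#' and larger than `meaningful_pp` percentage points in absolute value.
#'
#' @param diff_pp Difference in percentage points.
#' @param p_value Test probability (`NA` treated as not meaningful).
#' @param alpha Significance level, default 0.05.
#' @param meaningful_pp Practical-relevance threshold, default 10.
#' @return Logical vector.
#' @export
meaningful_difference <- function(diff_pp, p_value, alpha = 0.05,
                                  meaningful_pp = 10) {
  !is.na(p_value) & p_value < alpha & abs(diff_pp) > meaningful_pp
}

#' Compare consumption prevalence between the two methods
#'
#' Computes the percentage of matched respondent-days on which each method
#' reports consumption of `group`, their difference (questionnaire minus
#' recall, in percentage points), and a p-value from a linear probability
#' model: the stacked binary indicator regressed on a method fixed effect
#' with a respondent random intercept (fitted with
#' [lmerTest::lmer()]; Satterthwaite degrees of freedom). The random
#' intercept absorbs the dependence between the repeated observations of a
#' respondent.
#'
#' When the indicator is constant across both methods (all 0 or all 1) the
#' model is degenerate; the difference is 0 and the p-value `NA`.
#'
#' @inheritParams crosstab
#' @inheritParams meaningful_difference
#' @return One-row tibble: `group`, `p_dqq`, `p_r24h`, `diff_pp`,
#'   `p_value`, `meaningful`, `n` (matched observations).
#' @export
prevalence_comparison <- function(dqq_ind, recall_ind, group,
                                  alpha = 0.05, meaningful_pp = 10) {
  group <- check_group(group)
  keys <- c("respondent_id", "day")
  m <- inner_join(
    dqq_ind[, c(keys, group)] |> rename(dqq = all_of(group)),
    recall_ind[, c(keys, group)] |> rename(r24h = all_of(group)),
    by = keys
  )
  if (nrow(m) == 0) abort("No respondent-days matched across the two methods.")
  if (length(unique(m$respondent_id)) < 2) {
    abort("At least two respondents are required.")
  }

  p_dqq <- mean(m$dqq) * 100
  p_r24h <- mean(m$r24h) * 100
  diff_pp <- p_dqq - p_r24h

  long <- tibble(
    respondent_id = rep(m$respondent_id, 2),
    y = c(m$r24h, m$dqq),
    method = factor(rep(c("r24h", "dqq"), each = nrow(m)),
                    levels = c("r24h", "dqq"))
  )
  p_value <- if (sd(long$y) == 0) {
    NA_real_
  } else {
    fit <- suppressMessages(suppressWarnings(
      lmerTest::lmer(y ~ method + (1 | respondent_id), data = long,
                     REML = TRUE)
    ))
    ct <- stats::coef(summary(fit))
    unname(ct["methoddqq", "Pr(>|t|)"])
  }

  tibble(
    group = group, p_dqq = p_dqq, p_r24h = p_r24h, diff_pp = diff_pp,
    p_value = p_value,
    meaningful = meaningful_difference(diff_pp, p_value, alpha, meaningful_pp),
    n = nrow(m)
  )
}

#' Full per-group validation table
#'
#' Runs [prevalence_comparison()], [crosstab()] and [agreement_stats()] for
#' each of the six food groups and binds the results into the per-group
#' validation report.
#'
#' @inheritParams prevalence_comparison
#' @return A six-row tibble, one row per group, with prevalence, 2x2
#'   counts, agreement, misreporting and sensitivity/specificity columns.
#' @export
group_validation <- function(dqq_ind, recall_ind, alpha = 0.05,
                             meaningful_pp = 10) {
  rows <- lapply(fv_groups(), function(g) {
    pc <- prevalence_comparison(dqq_ind, recall_ind, g, alpha, meaningful_pp)
    t <- crosstab(dqq_ind, recall_ind, g)
    bind_cols(pc, tibble(a = t$a, b = t$b, c = t$c, d = t$d),
              agreement_stats(t))
  })
  bind_rows(rows)
}
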