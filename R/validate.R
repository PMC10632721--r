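#' Analysis configuration for the validation pipeline
#'
#' @param mode Recall scoring mode passed to [recall_indicators()].
#' @param min_grams Minimum item amount (g) in threshold-type modes.
#' @param threshold_basis Apply the minimum per item or per group total.
#' @param alpha Significance level for all tests.
#' @param meaningful_pp Practical-relevance threshold on prevalence
#'   differences, in percentage points.
#' @param cutoff Integer score cut-off for the adherence summary.
#' @param who_grams Gram-intake adherence threshold (g/day).
#' @param conf_level Confidence level for intervals.
#' @param seed Seed recorded in the run log (the validation itself is
#'   deterministic; the seed matters when the config drives a simulation).
#' @return Object of class `fv_config` (a named list).
#' @export
pipeline_config <- function(mode = "threshold", min_grams = 15,
                            threshold_basis = "item",
                            alpha = 0.05, meaningful_pp = 10,
                            cutoff = 3, who_grams = 400,
                            conf_level = 0.95, seed = 1L) {
  if (!is.finite(alpha) || alpha <= 0 || alpha >= 1) {
    abort("`alpha` must lie in (0, 1).")
  }
  if (!is.finite(meaningful_pp) || meaningful_pp <= 0) {
    abort("`meaningful_pp` must be positive.")
  }
  structure(
    list(mode = mode, min_grams = min_grams,
         threshold_basis = threshold_basis, alpha = alpha,
         meaningful_pp = meaningful_pp, cutoff = cutoff,
         who_grams = who_grams, conf_level = conf_level,
         seed = as.integer(seed)),
    class = "fv_config"
  )
}

#' Run the full method-validation pipeline on one dataset
#'
#' Executes every stage of the questionnaire-vs-recall comparison for a
#' single dataset (one country or survey per invocation): per-group
#' prevalence comparison and agreement statistics, paired Wilcoxon test on
#' the total score, standardized mixed-model slopes of gram intake on each
#' method's score, the dependent overlapping-correlation comparison
#' (Hittner z, Zou interval), and the Youden cut-off analysis against the
#' gram-intake adherence threshold.
#'
#' @param dqq Questionnaire table (see [read_dqq_table()]).
#' @param recall Item-level recall table (see [read_recall_table()]).
#' @param mapping An [fv_mapping()] object.
#' @param config An [pipeline_config()] object.
#' @return Object of class `fv_validation`: list with
#'   \describe{
#'     \item{groups}{per-group validation tibble (see
#'       [group_validation()]),}
#'     \item{scores}{matched per-observation tibble of both scores and
#'       gram intake,}
#'     \item{wilcoxon}{[wilcoxon_paired()] result on the matched scores,}
#'     \item{beta_st}{list with elements `r24h` and `dqq`: the
#'       [mixed_beta_st()] fits of intake on each score,}
#'     \item{correlations}{the [correlation_triple()],}
#'     \item{correlation_comparison}{[compare_dependent_correlations()]
#'       result,}
#'     \item{cutoff}{[cutoff_analysis()] result,}
#'     \item{log}{dropped-observation counts, unmapped-item count and the
#'       exact configuration.}
#'   }
#' @export
run_validation <- function(dqq, recall, mapping, config = pipeline_config()) {
  stopifnot(inherits(config, "fv_config"))
  dqq_ind <- dqq_indicators(dqq)
  rec_ind <- recall_indicators(
    recall, mapping, mode = config$mode, min_grams = config$min_grams,
    threshold_basis = config$threshold_basis, quiet = TRUE
  )
  n_unmapped <- attr(rec_ind, "n_unmapped") %||% 0L

  keys <- c("respondent_id", "day")
  matched <- inner_join(
    dqq_ind |> mutate(score_dqq = fv_gdr(dqq_ind)) |>
      select(all_of(c(keys, "score_dqq"))),
    rec_ind |> mutate(score_r24h = fv_gdr(rec_ind)) |>
      select(all_of(c(keys, "score_r24h"))),
    by = keys
  ) |>
    inner_join(total_intake(recall, mapping), by = keys)

  if (nrow(matched) == 0) {
    abort("Validation failed at matching: no respondent-days shared by the two methods.")
  }
  dropped_dqq <- nrow(dqq_ind) - nrow(matched)
  dropped_recall <- nrow(rec_ind) - nrow(matched)

  groups <- group_validation(dqq_ind, rec_ind, alpha = config$alpha,
                             meaningful_pp = config$meaningful_pp)

  wil <- wilcoxon_paired(matched$score_dqq, matched$score_r24h)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("Validation failed at stage `%s`: %s",
                    name, conditionMessage(e)))
    })
  }
  beta_r24h <- stage("beta_st_r24h", mixed_beta_st(
    matched$score_r24h, matched$total_grams, matched$respondent_id,
    conf_level = config$conf_level
  ))
  beta_dqq <- stage("beta_st_dqq", mixed_beta_st(
    matched$score_dqq, matched$total_grams, matched$respondent_id,
    conf_level = config$conf_level
  ))
  triple <- correlation_triple(matched$total_grams, matched$score_r24h,
                               matched$score_dqq)
  cor_cmp <- stage("correlation_comparison",
                   compare_dependent_correlations(triple,
                                                  conf_level = config$conf_level))
  cutoff <- stage("cutoff_analysis", cutoff_analysis(
    matched$score_dqq, matched$score_r24h, matched$total_grams,
    who_grams = config$who_grams, cutoff = config$cutoff
  ))

  structure(
    list(
      groups = groups, scores = matched, wilcoxon = wil,
      beta_st = list(r24h = beta_r24h, dqq = beta_dqq),
      correlations = triple, correlation_comparison = cor_cmp,
      cutoff = cutoff,
      log = list(
        n_matched = nrow(matched), dropped_dqq = dropped_dqq,
        dropped_recall = dropped_recall, n_unmapped_items = n_unmapped,
        config = unclass(config)
      )
    ),
    class = "fv_validation"
  )
}

#' @export
print.fv_validation <- function(x, ...) {
  cat(sprintf("Questionnaire vs recall validation (%d matched respondent-days)\n",
              x$log$n_matched))
  g <- x$groups
  cat("Per-group agreement (%):\n")
  for (i in seq_len(nrow(g))) {
    cat(sprintf(
      "  %-11s prev %5.1f vs %5.1f (diff %+6.1f pp%s)  agree %5.1f  FP %4.1f  FN %4.1f\n",
      g$group[i], g$p_dqq[i], g$p_r24h[i], g$diff_pp[i],
      ifelse(isTRUE(g$meaningful[i]), ", meaningful", ""),
      g$agreement_pct[i], g$fp_pct[i], g$fn_pct[i]
    ))
  }
  cat(sprintf("Wilcoxon paired score test: p = %.4g (median diff %g)\n",
              x$wilcoxon$p_value, x$wilcoxon$median_diff))
  cat(sprintf("beta_st intake ~ recall score: %.3f; ~ questionnaire score: %.3f\n",
              x$beta_st$r24h$beta_st, x$beta_st$dqq$beta_st))
  print(x$correlation_comparison)
  invisible(x)
}

#' Write a validation report to disk
#'
#' Writes the per-group table as CSV (percentages rounded to one decimal,
#' raw 2x2 counts kept unrounded) and the full result set, including the
#' run log and configuration, as JSON.
#'
#' @param report An `fv_validation` object.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_validation_report <- function(report, dir) {
  stopifnot(inherits(report, "fv_validation"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)

  g <- report$groups
  pct_cols <- c("p_dqq", "p_r24h", "diff_pp", "agreement_pct",
                "fp_pct", "fn_pct")
  for (cc in pct_cols) g[[cc]] <- round(g[[cc]], 1)
  g$sensitivity <- round(g$sensitivity, 3)
  g$specificity <- round(g$specificity, 3)
  readr::write_csv(g, file.path(dir, "groups.csv"))

  payload <- list(
    groups = report$groups,
    wilcoxon = report$wilcoxon,
    beta_st = lapply(report$beta_st, unclass),
    correlations = unclass(report$correlations),
    correlation_comparison = unclass(report$correlation_comparison),
    cutoff = lapply(unclass(report$cutoff), function(el) {
      if (inherits(el, "tbl_df")) as.data.frame(el) else el
    }),
    log = report$log
  )
  jsonlite::write_json(payload, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       pretty = TRUE)
  invisible(dir)
}
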