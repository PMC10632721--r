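# Shared validation for questionnaire tables (six {0,1} indicator columns).
check_dqq_table <- function(dqq, what = "questionnaire table") {
  required <- c("respondent_id", "day", fv_groups())
  missing <- setdiff(required, names(dqq))
  if (length(missing) > 0) {
    abort(sprintf("%s is missing column(s): %s.",
                  what, paste0("`", missing, "`", collapse = ", ")))
  }
  for (g in fv_groups()) {
    v <- dqq[[g]]
    ok <- !is.na(v) & (v == 0 | v == 1)
    if (!all(ok)) {
      abort(sprintf("%s column `%s` must contain only 0/1; see row %d.",
                    what, g, which(!ok)[1]))
    }
  }
  key <- paste(dqq$respondent_id, dqq$day, sep = "\r")
  if (anyDuplicated(key)) {
    d <- dqq[duplicated(key), , drop = FALSE]
    abort(sprintf("Duplicated (respondent_id, day): (\"%s\", %s).",
                  d$respondent_id[1], as.character(d$day[1])))
  }
  invisible(dqq)
}

check_recall_table <- function(recall, what = "recall table") {
  required <- c("respondent_id", "day", "item", "grams")
  missing <- setdiff(required, names(recall))
  if (length(missing) > 0) {
    abort(sprintf("%s is missing column(s): %s.",
                  what, paste0("`", missing, "`", collapse = ", ")))
  }
  g <- recall$grams
  bad <- is.na(g) | !is.finite(g) | g < 0
  if (any(bad)) {
    abort(sprintf(
      "%s column `grams` must be finite and non-negative; see row %d.",
      what, which(bad)[1]
    ))
  }
  invisible(recall)
}

#' Binary food-group indicators from questionnaire answers
#'
#' Converts a questionnaire response table (one row per respondent-day, six
#' yes/no answers coded 0/1) into an indicator table. The questionnaire asks
#' directly about each food group, so the indicators are the answers
#' themselves.
#'
#' @param dqq Data frame with columns `respondent_id`, `day`, and the six
#'   group columns of [fv_groups()], cells in {0,1}.
#' @return A tibble with columns `respondent_id`, `day`, `method`
#'   (`"dqq"`), and the six group indicator columns as integers.
#' @seealso [recall_indicators()] for the recall-derived counterpart.
#' @export
dqq_indicators <- function(dqq) {
  check_dqq_table(dqq)
  out <- as_tibble(dqq[, c("respondent_id", "day", fv_groups())])
  for (g in fv_groups()) out[[g]] <- as.integer(out[[g]])
  add_column(out, method = "dqq", .after = "day")
}

#' Binary food-group indicators from quantitative recall records
#'
#' Aggregates item-level recall records (grams consumed per food item) into
#' per-group consumption indicators for each respondent-day. Unmapped items
#' (non-fruit/vegetable foods) are ignored; their count is reported via
#' [rlang::inform()] and the `n_unmapped` attribute.
#'
#' Three scoring modes are supported:
#' \describe{
#'   \item{`threshold`}{a group counts as consumed if at least one of its
#'     items reaches `min_grams` (default 15 g). This is the mode used for
#'     comparison with the questionnaire, which lists only commonly consumed
#'     foods and is assumed to miss trace amounts.}
#'   \item{`all_quantities`}{any positive amount counts.}
#'   \item{`sentinel_only`}{as `threshold`, but only items flagged as
#'     sentinel in the mapping are eligible.}
#' }
#'
#' Duplicate rows of the same item on the same day are summed per
#' (respondent, day, item) before the threshold is applied. With
#' `threshold_basis = "group_total"` the `min_grams` rule is instead applied
#' to the per-group daily total, a sensitivity variant.
#'
#' @param recall Data frame with columns `respondent_id`, `day`, `item`,
#'   `grams` (finite, non-negative).
#' @param mapping An [fv_mapping()] object.
#' @param mode Scoring mode, see Details.
#' @param min_grams Minimum amount (g) for an item to count in `threshold`
#'   and `sentinel_only` modes. Must be positive.
#' @param threshold_basis Apply `min_grams` per item (default) or to the
#'   per-group daily total.
#' @param quiet Suppress the unmapped-item message.
#' @return A tibble with columns `respondent_id`, `day`, `method`
#'   (`"r24h"`), and the six group indicator columns; one row per
#'   respondent-day present in `recall`.
#' @export
recall_indicators <- function(recall, mapping,
                              mode = c("threshold", "all_quantities",
                                       "sentinel_only"),
                              min_grams = 15,
                              threshold_basis = c("item", "group_total"),
                              quiet = FALSE) {
  mode <- match.arg(mode)
  threshold_basis <- match.arg(threshold_basis)
  check_recall_table(recall)
  stopifnot(inherits(mapping, "fv_mapping"))
  if (mode != "all_quantities" && (!is.finite(min_grams) || min_grams <= 0)) {
    abort("`min_grams` must be positive in threshold and sentinel_only modes.")
  }

  frame <- distinct(as_tibble(recall[, c("respondent_id", "day")]))

  rec <- as_tibble(recall[, c("respondent_id", "day", "item", "grams")])
  rec$group <- classify_item(rec$item, mapping)
  n_unmapped <- sum(is.na(rec$group))
  if (n_unmapped > 0 && !quiet) {
    inform(sprintf("%d recall record(s) not in the mapping; excluded as non-fruit/vegetable items.",
                   n_unmapped))
  }
  rec <- rec[!is.na(rec$group), , drop = FALSE]
  if (mode == "sentinel_only") {
    rec <- rec[item_is_sentinel(rec$item, mapping), , drop = FALSE]
  }

  # sum duplicate item rows within a day before any threshold
  rec <- rec |>
    mutate(item = normalize_item(.data$item)) |>
    group_by(.data$respondent_id, .data$day, .data$group, .data$item) |>
    summarise(grams = sum(.data$grams), .groups = "drop")

  consumed <- if (mode == "all_quantities") {
    rec |> filter(.data$grams > 0)
  } else if (threshold_basis == "item") {
    rec |> filter(.data$grams >= min_grams)
  } else {
    rec |>
      group_by(.data$respondent_id, .data$day, .data$group) |>
      summarise(grams = sum(.data$grams), .groups = "drop") |>
      filter(.data$grams >= min_grams)
  }

  flags <- consumed |>
    distinct(.data$respondent_id, .data$day, .data$group) |>
    mutate(flag = 1L) |>
    tidyr::pivot_wider(names_from = "group", values_from = "flag",
                       values_fill = 0L)
  for (g in setdiff(fv_groups(), names(flags))) flags[[g]] <- 0L

  out <- frame |>
    left_join(flags, by = c("respondent_id", "day")) |>
    mutate(across(all_of(fv_groups()), ~ tidyr::replace_na(.x, 0L))) |>
    select(all_of(c("respondent_id", "day", fv_groups()))) |>
    add_column(method = "r24h", .after = "day")
  attr(out, "n_unmapped") <- n_unmapped
  out
}

#' Fruit-and-vegetable score from an indicator table
#'
#' The score for a respondent-day is the number of fruit and vegetable food
#' groups consumed, i.e. the sum of the six binary indicators, ranging from
#' 0 to 6.
#'
#' @param indicators Indicator table as returned by [dqq_indicators()] or
#'   [recall_indicators()].
#' @return Integer vector of scores, one per row.
#' @examples
#' ind <- tibble::tibble(respondent_id = "a", day = 1,
#'   va_veg = 1, dglv = 1, other_veg = 0, va_fruit = 0, citrus = 1,
#'   other_fruit = 0)
#' fv_gdr(ind)  # 3
#' @export
fv_gdr <- function(indicators) {
  missing <- setdiff(fv_groups(), names(indicators))
  if (length(missing) > 0) {
    abort(sprintf("Indicator table is missing group column(s): %s.",
                  paste0("`", missing, "`", collapse = ", ")))
  }
  m <- as.matrix(indicators[, fv_groups()])
  if (anyNA(m) || !all(m %in% c(0L, 1L))) {
    abort("Indicator values must all be 0 or 1.")
  }
  as.integer(rowSums(m))
}

#' Total fruit and vegetable intake in grams per day
#'
#' Sums the grams of every recall item mapped to any of the six food
#' groups, per respondent-day. No minimum-quantity filter is applied: the
#' 15 g rule concerns only the comparison of binary indicators, not gram
#' totals. Unmapped items are excluded.
#'
#' @inheritParams recall_indicators
#' @return A tibble `respondent_id`, `day`, `total_grams`; one row per
#'   respondent-day present in `recall` (0 when no mapped item was eaten).
#' @export
total_intake <- function(recall, mapping) {
  check_recall_table(recall)
  stopifnot(inherits(mapping, "fv_mapping"))
  frame <- distinct(as_tibble(recall[, c("respondent_id", "day")]))
  rec <- as_tibble(recall)
  rec$group <- classify_item(rec$item, mapping)
  totals <- rec |>
    filter(!is.na(.data$group)) |>
    group_by(.data$respondent_id, .data$day) |>
    summarise(total_grams = sum(.data$grams), .groups = "drop")
  frame |>
    left_join(totals, by = c("respondent_id", "day")) |>
    mutate(total_grams = tidyr::replace_na(.data$total_grams, 0))
}

#' Does a score meet an adherence cut-off?
#'
#' @param score Integer score(s) in 0..6.
#' @param cutoff Cut-off `k`; `TRUE` when `score >= k`.
#' @return Logical vector.
#' @export
meets_cutoff <- function(score, cutoff = 3) {
  if (any(score < 0 | score > 6, na.rm = TRUE)) {
    abort("`score` must lie in 0..6.")
  }
  score >= cutoff
}
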