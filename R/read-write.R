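# Read a CSV and fail early, naming any missing required column.
read_checked_csv <- function(path, required) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    abort(sprintf("%s is missing column(s): %s.",
                  path, paste0("`", missing, "`", collapse = ", ")))
  }
  df
}

#' Read a questionnaire response table
#'
#' Expects a CSV with columns `respondent_id`, `day`, and the six group
#' columns of [fv_groups()], cells coded 0/1. Duplicate (respondent, day)
#' rows, missing columns and non-binary cells are hard errors.
#'
#' @param path Path to the questionnaire CSV.
#' @return A validated tibble.
#' @export
read_dqq_table <- function(path) {
  df <- read_checked_csv(path, c("respondent_id", "day", fv_groups()))
  check_dqq_table(df, what = path)
  as_tibble(df)
}

#' Read an item-level recall table
#'
#' Expects a CSV with columns `respondent_id`, `day`, `item`, `grams`;
#' grams must parse as finite non-negative numbers.
#'
#' @param path Path to the recall CSV.
#' @return A validated tibble.
#' @export
read_recall_table <- function(path) {
  df <- read_checked_csv(path, c("respondent_id", "day", "item", "grams"))
  if (!is.numeric(df$grams)) {
    suppressWarnings(g <- as.numeric(df$grams))
    if (anyNA(g) & !anyNA(df$grams)) {
      abort(sprintf("Column `grams` in %s has unparseable value at row %d.",
                    path, which(is.na(g))[1]))
    }
    df$grams <- g
  }
  check_recall_table(df, what = path)
  as_tibble(df)
}

#' Write a simulated survey to disk
#'
#' Writes the questionnaire, recall and mapping tables of an `fv_sim`
#' object as CSV files (`dqq.csv`, `recall.csv`, `mapping.csv`), plus the
#' ground-truth ledgers (`truth_flags.csv`, `truth_totals.csv`).
#'
#' @param sim An object from [simulate_survey()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulated_data <- function(sim, dir) {
  stopifnot(inherits(sim, "fv_sim"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(sim$dqq, file.path(dir, "dqq.csv"))
  readr::write_csv(sim$recall, file.path(dir, "recall.csv"))
  m <- as_tibble(sim$mapping)
  m$sentinel <- as.integer(m$sentinel)
  readr::write_csv(m, file.path(dir, "mapping.csv"))
  readr::write_csv(sim$truth$flags, file.path(dir, "truth_flags.csv"))
  readr::write_csv(sim$truth$totals, file.path(dir, "truth_totals.csv"))
  invisible(dir)
}
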