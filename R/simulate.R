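# Recycle a scalar to a named per-group vector, or validate a length-6
# (optionally named) vector against the canonical group order.
per_group <- function(x, name) {
  groups <- fv_groups()
  if (length(x) == 1) {
    return(setNames(rep(as.numeric(x), 6), groups))
  }
  if (length(x) != 6) {
    abort(sprintf("`%s` must be a scalar or a vector of length 6.", name))
  }
  if (!is.null(names(x))) {
    missing <- setdiff(groups, names(x))
    if (length(missing) > 0) {
      abort(sprintf("`%s` is missing group(s): %s.", name,
                    paste(missing, collapse = ", ")))
    }
    x <- x[groups]
  } else {
    x <- setNames(as.numeric(x), groups)
  }
  as.numeric(x) |> setNames(groups)
}

check_prob <- function(x, name) {
  if (any(!is.finite(x) | x < 0 | x > 1)) {
    abort(sprintf("`%s` must lie in [0, 1].", name))
  }
  x
}

#' Configuration for the paired-survey simulator
#'
#' Collects every parameter of the synthetic data generator. Per-group
#' parameters accept a scalar (recycled) or a vector of length six, named
#' by [fv_groups()].
#'
#' The generator's latent model: each respondent carries a
#' consumption-propensity random effect `u ~ N(0, within_person_sd)` on the
#' logit scale, shared across recall days, so the two days of a respondent
#' are positively dependent. On each day, group `g` is consumed with
#' probability `plogis(qlogis(group_prevalence[g]) + u)`. A consumed group
#' contributes 1-3 recall items; item amounts are 15 g plus a lognormal
#' draw (so every ordinary portion clears the 15 g comparison rule),
#' except that with probability `small_portion_prob[g]` an item is a small
#' portion, Uniform(2, 14) g, emulating foods eaten as minor ingredients.
#' Each item is a sentinel item with probability `sentinel_coverage[g]`.
#' The questionnaire answer for a group is its latent consumption flag,
#' flipped 0 to 1 with probability `fp_prob[g]` (overreporting) and 1 to 0
#' with probability `fn_prob[g]` (underreporting).
#'
#' @param n_respondents Number of respondents.
#' @param days_per_respondent Recall days per respondent (default 2).
#' @param group_prevalence Per-group marginal consumption probability.
#' @param within_person_sd SD of the respondent random effect (logit scale).
#' @param quantity_log_mean,quantity_log_sd Per-group lognormal parameters
#'   of the item amount above 15 g.
#' @param small_portion_prob Per-group probability that a consumed item is
#'   a sub-15 g portion.
#' @param fp_prob,fn_prob Per-group questionnaire false-positive /
#'   false-negative probabilities.
#' @param sentinel_coverage Per-group probability that a consumed item is a
#'   sentinel item.
#' @param seed Integer seed; the simulation is fully reproducible given it.
#' @return Object of class `fv_sim_config` (a named list).
#' @seealso [simulate_survey()], [scenario_presets()]
#' @export
simulation_config <- function(n_respondents = 600,
                              days_per_respondent = 2,
                              group_prevalence = c(
                                va_veg = 0.35, dglv = 0.75, other_veg = 0.90,
                                va_fruit = 0.20, citrus = 0.30,
                                other_fruit = 0.55
                              ),
                              within_person_sd = 0.8,
                              quantity_log_mean = log(45),
                              quantity_log_sd = 0.6,
                              small_portion_prob = 0,
                              fp_prob = 0,
                              fn_prob = 0,
                              sentinel_coverage = 0.8,
                              seed = 20211001L) {
  if (!is.finite(n_respondents) || n_respondents < 1 ||
      n_respondents != round(n_respondents)) {
    abort("`n_respondents` must be a positive integer.")
  }
  if (!is.finite(days_per_respondent) || days_per_respondent < 1 ||
      days_per_respondent != round(days_per_respondent)) {
    abort("`days_per_respondent` must be a positive integer.")
  }
  if (!is.finite(within_person_sd) || within_person_sd < 0) {
    abort("`within_person_sd` must be non-negative.")
  }
  cfg <- list(
    n_respondents = as.integer(n_respondents),
    days_per_respondent = as.integer(days_per_respondent),
    group_prevalence = check_prob(per_group(group_prevalence,
                                            "group_prevalence"),
                                  "group_prevalence"),
    within_person_sd = within_person_sd,
    quantity_log_mean = per_group(quantity_log_mean, "quantity_log_mean"),
    quantity_log_sd = per_group(quantity_log_sd, "quantity_log_sd"),
    small_portion_prob = check_prob(per_group(small_portion_prob,
                                              "small_portion_prob"),
                                    "small_portion_prob"),
    fp_prob = check_prob(per_group(fp_prob, "fp_prob"), "fp_prob"),
    fn_prob = check_prob(per_group(fn_prob, "fn_prob"), "fn_prob"),
    sentinel_coverage = check_prob(per_group(sentinel_coverage,
                                             "sentinel_coverage"),
                                   "sentinel_coverage"),
    seed = as.integer(seed)
  )
  if (any(cfg$quantity_log_sd < 0)) {
    abort("`quantity_log_sd` must be non-negative.")
  }
  structure(cfg, class = "fv_sim_config")
}

# Synthetic item pools: three sentinel and three non-sentinel items per
# group. Names are deliberately schematic; this is generated data, not a
# country food list.
simulated_mapping <- function() {
  groups <- rep(fv_groups(), each = 6)
  idx <- rep(c(1:3, 1:3), times = 6)
  kind <- rep(rep(c("s", "n"), each = 3), times = 6)
  fv_mapping(
    item = paste0(groups, "_", kind, idx),
    group = groups,
    sentinel = kind == "s",
    country_tag = "synthetic"
  )
}

#' Simulate a paired questionnaire/recall survey with known truth
#'
#' Generates, from an [simulation_config()], a questionnaire table, an
#' item-level recall table, the item-to-group mapping used, and the latent
#' ground truth, structured like a two-day dual-method dietary survey. The
#' recall table records consumed items and gram amounts faithfully (all
#' misreporting is injected into the questionnaire answers); every
#' respondent-day also contains one unmapped staple item (`rice`), so each
#' respondent-day is present in the recall table even when no fruit or
#' vegetable was consumed.
#'
#' @param config An `fv_sim_config` object.
#' @return Object of class `fv_sim`: list with elements
#'   \describe{
#'     \item{dqq}{questionnaire table (`respondent_id`, `day`, six 0/1
#'       group columns),}
#'     \item{recall}{item-level table (`respondent_id`, `day`, `item`,
#'       `grams`),}
#'     \item{mapping}{the [fv_mapping()] used,}
#'     \item{truth}{list of `flags` (latent consumption per
#'       respondent-day-group, before questionnaire error injection) and
#'       `totals` (true fruit-and-vegetable grams per respondent-day),}
#'     \item{config}{the configuration.}
#'   }
#' @examples
#' sim <- simulate_survey(simulation_config(n_respondents = 10, seed = 1))
#' head(sim$recall)
#' @export
simulate_survey <- function(config) {
  if (!inherits(config, "fv_sim_config")) {
    abort("`config` must be created by `simulation_config()`.")
  }
  set.seed(config$seed)
  groups <- fv_groups()
  n <- config$n_respondents
  days <- config$days_per_respondent
  ids <- sprintf("R%04d", seq_len(n))

  u <- rnorm(n, 0, config$within_person_sd)

  grid <- tidyr::expand_grid(
    respondent_id = ids, day = seq_len(days), group = groups
  )
  grid$u <- u[match(grid$respondent_id, ids)]
  pi_g <- config$group_prevalence[grid$group]
  grid$p <- plogis(qlogis(pi_g) + grid$u)
  grid$latent <- rbinom(nrow(grid), 1, grid$p)

  # recall items for consumed groups
  consumed <- grid[grid$latent == 1, c("respondent_id", "day", "group")]
  n_items <- sample(1:3, nrow(consumed), replace = TRUE)
  items <- consumed[rep(seq_len(nrow(consumed)), n_items), , drop = FALSE]
  k <- nrow(items)
  g <- items$group
  sentinel <- runif(k) < config$sentinel_coverage[g]
  slot <- sample(1:3, k, replace = TRUE)
  items$item <- paste0(g, "_", ifelse(sentinel, "s", "n"), slot)
  grams <- 15 + rlnorm(k, config$quantity_log_mean[g], config$quantity_log_sd[g])
  small <- runif(k) < config$small_portion_prob[g]
  grams[small] <- runif(sum(small), 2, 14)
  items$grams <- round(grams, 1)

  # one unmapped staple row per respondent-day keeps every respondent-day
  # in the recall table
  staple <- tidyr::expand_grid(respondent_id = ids, day = seq_len(days))
  staple$item <- "rice"
  staple$grams <- round(15 + rlnorm(nrow(staple), log(150), 0.3), 1)

  recall <- bind_rows(
    items[, c("respondent_id", "day", "item", "grams")],
    staple
  ) |>
    arrange(.data$respondent_id, .data$day, .data$item)

  # questionnaire: latent flag with group-level flips
  ans <- grid$latent
  flip_up <- runif(nrow(grid)) < config$fp_prob[grid$group]
  flip_down <- runif(nrow(grid)) < config$fn_prob[grid$group]
  ans[grid$latent == 0 & flip_up] <- 1L
  ans[grid$latent == 1 & flip_down] <- 0L
  dqq <- grid |>
    mutate(answer = ans) |>
    select(all_of(c("respondent_id", "day", "group", "answer"))) |>
    tidyr::pivot_wider(names_from = "group", values_from = "answer") |>
    select(all_of(c("respondent_id", "day", groups))) |>
    arrange(.data$respondent_id, .data$day)

  truth_flags <- grid |>
    select(all_of(c("respondent_id", "day", "group", "latent"))) |>
    arrange(.data$respondent_id, .data$day, .data$group)
  truth_totals <- items |>
    group_by(.data$respondent_id, .data$day) |>
    summarise(total_grams = sum(.data$grams), .groups = "drop") |>
    right_join(distinct(staple[, c("respondent_id", "day")]),
               by = c("respondent_id", "day")) |>
    mutate(total_grams = tidyr::replace_na(.data$total_grams, 0)) |>
    arrange(.data$respondent_id, .data$day)

  structure(
    list(dqq = dqq, recall = recall, mapping = simulated_mapping(),
         truth = list(flags = truth_flags, totals = truth_totals),
         config = config),
    class = "fv_sim"
  )
}

#' @export
print.fv_sim <- function(x, ...) {
  cat(sprintf(
    "Simulated dual-method survey: %d respondents x %d day(s), seed %d\n",
    x$config$n_respondents, x$config$days_per_respondent, x$config$seed
  ))
  cat(sprintf("  %d questionnaire rows, %d recall records\n",
              nrow(x$dqq), nrow(x$recall)))
  invisible(x)
}

#' Ready-made simulation scenarios
#'
#' Named [simulation_config()] presets exercising qualitatively different
#' misreporting regimes:
#' \describe{
#'   \item{`no_error`}{no questionnaire error and no small portions: the
#'     questionnaire must agree perfectly with threshold-mode recall
#'     indicators.}
#'   \item{`hanoi_like`}{a vegetable-rich diet where the questionnaire
#'     underreports the high-variety groups (`other_veg`, `other_fruit`,
#'     which also have low sentinel coverage) and mildly overreports dark
#'     green leafy vegetables and citrus.}
#'   \item{`ibadan_like`}{vitamin A-rich vegetables are eaten frequently
#'     but mostly as small (sub-15 g) sauce ingredients, so the
#'     questionnaire overreports them relative to threshold-mode recall;
#'     fruit groups are rare, well-listed and accurately reported.}
#' }
#'
#' @return Named list of `fv_sim_config` objects with fixed default seeds.
#' @export
scenario_presets <- function() {
  list(
    no_error = simulation_config(
      n_respondents = 600,
      small_portion_prob = 0, fp_prob = 0, fn_prob = 0,
      seed = 20210101L
    ),
    hanoi_like = simulation_config(
      n_respondents = 600,
      group_prevalence = c(va_veg = 0.30, dglv = 0.80, other_veg = 0.95,
                           va_fruit = 0.20, citrus = 0.30,
                           other_fruit = 0.70),
      fp_prob = c(va_veg = 0.04, dglv = 0.12, other_veg = 0.04,
                  va_fruit = 0.04, citrus = 0.12, other_fruit = 0.04),
      fn_prob = c(va_veg = 0.03, dglv = 0.03, other_veg = 0.28,
                  va_fruit = 0.03, citrus = 0.03, other_fruit = 0.28),
      sentinel_coverage = c(va_veg = 0.85, dglv = 0.85, other_veg = 0.45,
                            va_fruit = 0.85, citrus = 0.85,
                            other_fruit = 0.45),
      small_portion_prob = 0.05,
      seed = 20210102L
    ),
    ibadan_like = simulation_config(
      n_respondents = 600,
      group_prevalence = c(va_veg = 0.85, dglv = 0.45, other_veg = 0.90,
                           va_fruit = 0.10, citrus = 0.15,
                           other_fruit = 0.35),
      small_portion_prob = c(va_veg = 0.55, dglv = 0.03, other_veg = 0.03,
                             va_fruit = 0.03, citrus = 0.03,
                             other_fruit = 0.03),
      fp_prob = c(va_veg = 0.12, dglv = 0.12, other_veg = 0.02,
                  va_fruit = 0.02, citrus = 0.02, other_fruit = 0.02),
      fn_prob = 0.02,
      sentinel_coverage = 0.9,
      seed = 20210103L
    )
  )
}
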