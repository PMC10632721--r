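test_that("invalid configurations are rejected before any draw", {
  expect_error(simulation_config(n_respondents = 0), "positive integer")
  expect_error(simulation_config(group_prevalence = 1.2), "\\[0, 1\\]")
  expect_error(simulation_config(fp_prob = -0.1), "\\[0, 1\\]")
  expect_error(simulation_config(within_person_sd = -1), "non-negative")
  expect_error(simulation_config(group_prevalence = c(a = 0.5, b = 0.5)),
               "length 6")
})

test_that("simulation is fully reproducible given the seed", {
  cfg <- simulation_config(n_respondents = 50, seed = 99L)
  s1 <- simulate_survey(cfg)
  s2 <- simulate_survey(cfg)
  expect_identical(s1$dqq, s2$dqq)
  expect_identical(s1$recall, s2$recall)
  expect_identical(s1$truth, s2$truth)
  s3 <- simulate_survey(simulation_config(n_respondents = 50, seed = 100L))
  expect_false(identical(s1$recall, s3$recall))
})

test_that("with no error injection, questionnaire equals threshold recall indicators", {
  cfg <- simulation_config(n_respondents = 120, small_portion_prob = 0,
                           fp_prob = 0, fn_prob = 0, seed = 7L)
  sim <- simulate_survey(cfg)
  dqq_ind <- dqq_indicators(sim$dqq)
  rec_ind <- recall_indicators(sim$recall, sim$mapping, quiet = TRUE)
  keys <- c("respondent_id", "day")
  m <- merge(dqq_ind, rec_ind, by = keys, suffixes = c("_q", "_r"))
  for (g in fv_groups()) {
    expect_equal(m[[paste0(g, "_q")]], m[[paste0(g, "_r")]])
  }
  # truth flags equal the recall-derived indicators before error injection
  truth_wide <- tidyr::pivot_wider(sim$truth$flags, names_from = "group",
                                   values_from = "latent")
  m2 <- merge(rec_ind, truth_wide, by = keys, suffixes = c("_r", "_t"))
  for (g in fv_groups()) {
    expect_equal(m2[[paste0(g, "_r")]], as.integer(m2[[paste0(g, "_t")]]))
  }
})

test_that("configured prevalence is recovered by recall-derived indicators", {
  cfg <- simulation_config(n_respondents = 2500, days_per_respondent = 2,
                           seed = 500L)
  sim <- simulate_survey(cfg)
  rec_ind <- recall_indicators(sim$recall, sim$mapping,
                               mode = "all_quantities", quiet = TRUE)
  n_obs <- nrow(rec_ind)
  for (g in fv_groups()) {
    pi_g <- cfg$group_prevalence[[g]]
    p_hat <- mean(rec_ind[[g]])
    # 3 Monte-Carlo SEs, inflated for the within-person dependence
    # (two days per respondent give fewer than n_obs independent draws)
    se <- sqrt(pi_g * (1 - pi_g) / (n_obs / 2))
    expect_lt(abs(p_hat - pi_g), 3 * se + 0.02)
  }
})

test_that("small portions depress threshold-mode prevalence only", {
  base <- list(n_respondents = 800, seed = 321L)
  p_thr <- c(); p_all <- c()
  for (sp in c(0, 0.35, 0.7)) {
    cfg <- simulation_config(n_respondents = base$n_respondents,
                             small_portion_prob = c(
                               va_veg = sp, dglv = 0, other_veg = 0,
                               va_fruit = 0, citrus = 0, other_fruit = 0),
                             seed = base$seed)
    sim <- simulate_survey(cfg)
    thr <- recall_indicators(sim$recall, sim$mapping, quiet = TRUE)
    all <- recall_indicators(sim$recall, sim$mapping,
                             mode = "all_quantities", quiet = TRUE)
    p_thr <- c(p_thr, mean(thr$va_veg))
    p_all <- c(p_all, mean(all$va_veg))
  }
  expect_true(all(diff(p_thr) < 0))          # strictly decreasing
  expect_lt(max(abs(diff(p_all))), 0.03)     # unchanged in expectation
})

test_that("lower sentinel coverage raises questionnaire FP in sentinel-only comparisons", {
  fp <- c()
  for (cov in c(0.9, 0.5, 0.2)) {
    cfg <- simulation_config(n_respondents = 500,
                             sentinel_coverage = cov, seed = 77L)
    sim <- simulate_survey(cfg)
    dqq_ind <- dqq_indicators(sim$dqq)
    sen_ind <- recall_indicators(sim$recall, sim$mapping,
                                 mode = "sentinel_only", quiet = TRUE)
    t <- crosstab(dqq_ind, sen_ind, "other_veg")
    fp <- c(fp, misreport_rates(t)[["fp_pct"]])
  }
  expect_true(all(diff(fp) > 0))
})

test_that("scenario presets are named, distinct and behave as labelled", {
  presets <- scenario_presets()
  expect_true(all(c("no_error", "hanoi_like", "ibadan_like") %in%
                    names(presets)))
  expect_false(anyDuplicated(names(presets)) > 0)
  ne <- presets$no_error
  expect_true(all(ne$fp_prob == 0) && all(ne$fn_prob == 0) &&
                all(ne$small_portion_prob == 0))

  # small-portion overreporting scenario: questionnaire FP concentrates on
  # vitamin A-rich vegetables, exceeding every fruit group
  sim <- simulate_survey(presets$ibadan_like)
  dqq_ind <- dqq_indicators(sim$dqq)
  rec_ind <- recall_indicators(sim$recall, sim$mapping, quiet = TRUE)
  fp <- vapply(fv_groups(), function(g) {
    misreport_rates(crosstab(dqq_ind, rec_ind, g))[["fp_pct"]]
  }, numeric(1))
  expect_true(all(fp[["va_veg"]] > fp[c("va_fruit", "citrus", "other_fruit")]))
})
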