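---
title: "Validating a list-based fruit-and-vegetable score: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating a list-based fruit-and-vegetable score: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fvgdr)
```

## What is being validated

A cheap yes/no questionnaire asks whether any food from a short list of
sentinel items in each of six fruit-and-vegetable food groups was eaten the
previous day. Summing the six answers gives a 0–6 score per respondent-day.
The reference is a quantitative 24-hour recall of the same day, which
records every food item and its amount in grams. `fvgdr` computes, for one
dataset at a time, the statistics needed to judge whether the
questionnaire-derived score can stand in for the recall-derived one at the
population level.

Both instruments are observed twice per respondent (two non-consecutive
days), so almost every analysis below has to cope with within-person
dependence; that is the single modelling thread running through the
package.

## Deriving the indicators

The questionnaire *is* a set of six binary indicators. The recall is
item-level, so items are first classified by an item-to-group mapping
(`fv_mapping()`; exact lookup after case-folding and whitespace
normalisation — deterministic and auditable, no fuzzy matching). Items not
in the mapping are non-fruit/vegetable foods: they are excluded and
counted, never an error.

A recall item only counts towards an indicator when at least **15 g** was
eaten (inclusive boundary — "at least"), because the questionnaire targets
commonly consumed foods and is assumed to miss trace amounts eaten inside
mixed dishes. Three decisions around this rule are worth making explicit:

* The rule is applied **per food item**, not per group total: it describes
  a property of a food as consumed. Duplicate rows of the same item on the
  same day are summed first, so data-entry granularity cannot flip an
  indicator. Whether the rule should instead apply to the per-group daily
  total is a genuinely open question; `threshold_basis = "group_total"`
  provides that variant for sensitivity analysis.
* Two alternative scoring modes mirror the natural sensitivity analyses:
  `all_quantities` (any positive amount counts) and `sentinel_only`
  (restrict to items flagged as sentinel in the mapping, emulating what the
  questionnaire could at best see).
* **Gram totals are never filtered**: total fruit-and-vegetable intake per
  day sums every mapped item regardless of amount. The 15 g rule exists
  only for the indicator comparison.

These modes are nested (`all_quantities` ⊇ `threshold` ⊇ `sentinel_only`
in eligible items), which the test suite checks as a property: the score
can only decrease along that chain.

## Agreement battery

For each group, matched respondent-days are cross-tabulated into `a` (both
methods negative), `b` (questionnaire only — false positive, type I), `c`
(recall only — false negative, type II), `d` (both positive). From this:

* percentage agreement `((a+d)/n)·100`;
* misreporting rates `b/n` and `c/n`, *over all observations* rather than
  over the positive/negative margins — this is the only convention under
  which agreement + FP + FN partitions 100%, which makes the three numbers
  mutually auditable;
* sensitivity `d/(c+d)` and specificity `a/(a+b)` of the questionnaire
  with the recall as reference. A rate whose denominator is zero is
  reported as `NA`: a rate that was never at risk is not 0, it is
  unobservable.

The prevalence difference per group (questionnaire minus recall, in
percentage points) is tested with a **linear probability model**: the
stacked binary indicator regressed on a method effect with a respondent
random intercept, fitted by REML (`lmerTest`, Satterthwaite df). A logistic
link would be the other defensible choice; the linear model was chosen
because the estimand is exactly the difference in proportions, its scale is
the one the meaningfulness rule below is defined on, and for prevalences
away from 0/1 with this design the two give practically identical p-values.
When an indicator is constant everywhere the model is degenerate: the
difference is 0 and the p-value `NA`, never fabricated.

A difference is flagged **meaningful** only when `p < 0.05` *and* it
exceeds **10 percentage points** in absolute value — a dual rule that keeps
trivially small but significant differences (large n makes everything
significant) from being over-read.

## Score-level inference

* **Paired Wilcoxon signed-rank test** on the per-observation score
  differences; zero differences are discarded, p-values use the
  tie-corrected normal approximation (scores are small integers, ties are
  the norm, an exact distribution is unavailable). If every difference is
  zero the test is vacuous and reported as statistic 0, p = 1. The test
  treats respondent-days as exchangeable pairs; it ignores the
  day-within-respondent structure, as is conventional for this battery.
* **Standardized mixed-model slopes.** Gram intake and score are
  z-standardized over all observations; then
  `intake* = beta_st · score* + u_respondent + e` is fitted by REML. The
  standardized slope acts as a correlation-like effect size that respects
  clustering. Confidence intervals are Wald (`beta ± 1.96·se`): cheap,
  standard for this kind of reporting, and pinned by an exact oracle in the
  no-clustering limit. Two numerical edges are handled explicitly: with one
  observation per respondent the random intercept is unidentifiable and the
  fit *is* standardized OLS, so that is what the function computes; a
  perfect linear relation has no residual variance and is returned as
  slope ±1 with a collapsed interval rather than pushed through a
  degenerate REML fit.
* **Dependent overlapping correlations.** Intake correlates with each
  method's score; the two correlations share the intake variable, so their
  difference cannot be tested as if independent. Two complementary
  procedures are computed from `(r12, r13, r23, n)`: Hittner's z (difference
  of Fisher z's scaled by a joint standard error whose covariance term is
  evaluated at the mean of the two overlapping correlations) and Zou's
  confidence interval for `r12 − r13` (assembled from the individual Fisher
  interval limits and the estimated correlation between the two sample
  correlations). When `r12 = r13` exactly — which happens legitimately,
  e.g. when the two methods agree perfectly and `r23 = 1` — the scale
  factor of the z statistic is 0/0; the statistic's own limit is used:
  z = 0, p = 1. Inputs with `|r| = 1` are refused (Fisher transform
  undefined), as are correlation triples that are not positive
  semi-definite.

  The correlations fed to this test are plain product-moment correlations
  over all observations, clustering ignored, because the test's reference
  distribution assumes independent observations. The cluster-respecting
  `beta_st` answers the same question under the mixed model; both are
  reported side by side and the discrepancy between them is information,
  not error.
* **Cut-off analysis.** Observations are labelled by whether total intake
  reaches 400 g/day (the WHO adherence recommendation; configurable), and
  every half-integer cut-off −0.5, 0.5, …, 6.5 of each score is scored by
  Youden's J = sensitivity + specificity − 1. Half-integers because the
  score is integer-valued: cutting between attainable values makes the
  sweep exhaustive. Youden's J is this package's criterion choice — it
  weighs the two error types equally and is the standard default for
  selecting a classification threshold when no asymmetric cost is given. Ties are broken
  toward the lowest cut-off. The proportion of observations at/above a
  supplied integer cut-off (default 3) is reported per method alongside.

## The synthetic-data generator

Field data of this kind is rarely shareable, so every pipeline stage is
exercised on simulated surveys with known truth (`simulate_survey()`):

* Each respondent has a consumption-propensity random effect
  `u ~ N(0, within_person_sd)` on the logit scale (default SD 0.8, a
  moderate intraclass correlation), shared across the two days — this is
  precisely the dependence the mixed models exist to absorb.
* On each day, group `g` is consumed with probability
  `logistic(logit(pi_g) + u)`; a consumed group contributes 1–3 items.
* Item amounts are **15 g + lognormal** (defaults: median ≈ 60 g, log-SD
  0.6 — right-skewed, strictly positive, portion-sized). The 15 g shift
  makes every ordinary portion clear the threshold rule, so that with no
  error injection the questionnaire and the threshold-mode recall
  indicators agree *exactly* — an identity the suite relies on. With
  probability `small_portion_prob[g]` an item is instead a small portion,
  Uniform(2, 14) g: a food eaten as a minor ingredient, invisible to
  threshold scoring but visible to `all_quantities`.
* Each item is a sentinel item with probability `sentinel_coverage[g]`.
* Questionnaire error is injected at the group level (the questionnaire
  only observes group-level yes/no): a true non-consumption flips to "yes"
  with probability `fp_prob[g]`, a true consumption to "no" with
  `fn_prob[g]`.
* Every respondent-day also contains one unmapped staple item (rice), so
  each respondent-day exists in the recall table even when no fruit or
  vegetable was eaten.

Three presets span the regimes of interest: `no_error` (perfect agreement
benchmark), `hanoi_like` (underreporting of the high-variety groups, low
sentinel coverage there), and `ibadan_like` (vitamin A-rich vegetables
eaten frequently but mostly as sub-15 g sauce ingredients, hence
questionnaire overreporting concentrated on that group). Defaults use 600
respondents × 2 days, the scale of one country arm of a typical validation
survey.

Two monotonicities document the generator's logic and are tested: raising
`small_portion_prob` depresses threshold-mode prevalence while leaving
`all_quantities` prevalence unchanged in expectation (so switching modes
shrinks an overreporting gap); and lowering `sentinel_coverage` raises the
questionnaire's *false-positive* rate against sentinel-only recall scoring
— the recall loses positives, so discrepancies move into the
questionnaire-only cell, not the recall-only one.

What the generator does **not** emulate: day-of-week and seasonal menus,
correlated errors between the two instruments (both rely on the same
memory of the same day — in real data this inflates agreement), recall
underreporting of episodic foods, portion-size measurement error, and
recipe disaggregation. Passing tests therefore demonstrate that the
statistical machinery is correct and calibrated under a clean, known
truth — not that any particular field instrument is valid.

## Problem sizes and calibration checks

The test suite's statistical checks use sizes chosen to keep Monte-Carlo
error well inside the asserted bands: misreporting-rate recovery at 5 000
respondents × 2 days against a closed-form expectation (within 3
Monte-Carlo standard errors); null calibration of the Hittner z over 1 000
trivariate-normal replicates of n = 300 (type-I error asserted in
[0.03, 0.07], Zou coverage in [93%, 97%]); Wald-interval coverage of the
mixed-model slope over 100 replicates of 500 respondents × 2 days
(≥ 90/100); and the attenuation ordering — questionnaire-derived slope
below recall-derived slope whenever questionnaire misclassification is
present — over 50 replicates of the two error presets (≥ 45/50).
Permutation (sign-flip), bootstrap and brute-force enumeration oracles back
the Wilcoxon p-value, the Zou interval and the agreement/Youden
computations on small instances.

## Limitations

* One dataset per invocation; no pooled multi-country mode and no survey
  weights.
* No chance-corrected agreement (kappa) and no multiple-testing correction
  across the six groups — the battery reports six parallel comparisons and
  leaves the familywise question to the reader.
* The linear probability model can in principle predict outside [0, 1];
  for prevalence testing at these sample sizes this is immaterial, but the
  p-values should not be reused as a risk model.
* The shipped example mapping is illustrative. Real analyses must supply
  the item-to-group dictionary of their own instrument and country.
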