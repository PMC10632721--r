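# fvgdr

Validation toolkit for list-based fruit-and-vegetable food-group scores.

## The problem

Quantitative 24-hour recalls (24hR) measure what people actually ate, in
grams, but they are expensive: trained interviewers, multi-pass protocols,
recipe databases. A list-based yes/no questionnaire such as the Diet
Quality Questionnaire (DQQ) asks only whether any food from a short list
of common ("sentinel") items was eaten the previous day, and can be fielded
at a fraction of the cost. The fruit-and-vegetable score considered here
counts how many of six food groups were consumed —

1. vitamin A-rich vegetables, 2. dark green leafy vegetables,
3. other vegetables, 4. vitamin A-rich fruits, 5. citrus, 6. other fruits

— giving an integer score from 0 to 6 per respondent-day. Before such a
score can be used for population monitoring, it has to be validated against
a reference method: does the questionnaire-derived score estimate food-group
consumption prevalence, and track actual gram intake, as well as the score
derived from the recall itself?

`fvgdr` implements that validation battery end to end, for anyone comparing
a list-based instrument against a quantitative recall:

- **Scoring.** Binary per-group indicators from questionnaire answers and
  from item-level recall records (a recall item counts only when ≥ 15 g was
  eaten, since the questionnaire targets commonly consumed foods; variants
  with all quantities or sentinel items only are available), the 0–6 score,
  and total fruit-and-vegetable grams/day.
- **Agreement.** Per group: prevalence by each method and their difference
  (tested with a linear probability model with a respondent random
  intercept, so repeated days of one person are handled), the 2×2
  cross-tabulation, percentage agreement `((a+d)/n)·100`, false-positive
  and false-negative percentages (over all observations, so
  agreement + FP + FN = 100), and sensitivity/specificity of the
  questionnaire against the recall reference.
- **Score-level inference.** Paired Wilcoxon signed-rank test; standardized
  slopes `beta_st` of gram intake on each method's score from
  random-intercept linear mixed models; the comparison of the two dependent
  overlapping correlations (Hittner's z, Zou's confidence interval for the
  difference); and a Youden-index sweep of half-integer score cut-offs
  against the 400 g/day adherence threshold.
- **Simulation.** A paired-survey generator with known ground truth:
  within-person correlation across the two recall days, per-group
  consumption prevalence, lognormal item amounts, small-portion events,
  sentinel coverage, and configurable questionnaire false-positive /
  false-negative rates. Presets reproduce qualitatively distinct
  misreporting regimes.

## Worked example

Simulate a survey of 600 respondents × 2 recall days in which the
questionnaire underreports the two high-variety groups (other vegetables,
other fruits), then run the full validation:

```r
library(fvgdr)

sim <- simulate_survey(scenario_presets()$hanoi_like)
report <- run_validation(sim$dqq, sim$recall, sim$mapping)
print(report)
```

```
Questionnaire vs recall validation (1200 matched respondent-days)
Per-group agreement (%):
  va_veg      prev  33.2 vs  30.7 (diff   +2.6 pp)  agree  95.2  FP  3.7  FN  1.1
  dglv        prev  79.3 vs  76.7 (diff   +2.7 pp)  agree  93.7  FP  4.5  FN  1.8
  other_veg   prev  67.4 vs  91.9 (diff  -24.5 pp, meaningful)  agree  72.3  FP  1.6  FN 26.1
  va_fruit    prev  25.3 vs  22.8 (diff   +2.6 pp)  agree  96.2  FP  3.2  FN  0.6
  citrus      prev  37.5 vs  30.2 (diff   +7.2 pp)  agree  90.4  FP  8.4  FN  1.2
  other_fruit prev  50.8 vs  67.7 (diff  -16.8 pp, meaningful)  agree  79.2  FP  2.0  FN 18.8
Wilcoxon paired score test: p = 2.832e-27 (median diff 0)
beta_st intake ~ recall score: 0.780; ~ questionnaire score: 0.620
Dependent overlapping correlations: r12 - r13 = 0.158
  Hittner z = 13.007 (p = 1.124e-38); Zou 95% CI (0.133, 0.185)
```

Reading the output: the questionnaire misses about a quarter of
other-vegetable consumption (−24.5 percentage points, flagged *meaningful*
because the gap is both significant at the 5% level and larger than 10
points), agreement stays above 90% for the well-listed groups, and the
score still tracks gram intake — but less strongly when derived from the
questionnaire (`beta_st` 0.62 vs 0.78). The Hittner z and the Zou interval
confirm that attenuation is real rather than sampling noise.
`write_validation_report(report, dir)` saves the per-group table as CSV and
everything else, including the run log and configuration, as JSON. A thin
command-line wrapper with `simulate`, `score` and `validate` subcommands is
installed under `inst/cli/fvgdr`.

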