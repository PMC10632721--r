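Package: fvgdr
Title: Validating Fruit and Vegetable Food-Group Scores Against Quantitative Recalls
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for assessing how well a list-based yes/no dietary
    questionnaire measures fruit and vegetable intake relative to a
    quantitative 24-hour recall. Derives binary food-group indicators and
    the six-group fruit-and-vegetable score from both assessment methods,
    computes the method-comparison battery (prevalence differences tested
    with random-intercept linear mixed models, two-by-two tables,
    percentage agreement, sensitivity, specificity, type I/II misreporting
    rates), score-level inference (paired Wilcoxon test, standardized
    mixed-model slopes of intake on score, Zou confidence intervals and
    Hittner z tests for dependent overlapping correlations, Youden-index
    cut-off analysis), and simulates paired questionnaire/recall survey
    data with known ground truth for end-to-end checking.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    lme4,
    lmerTest,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    MASS,
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
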