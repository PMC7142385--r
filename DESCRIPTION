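Package: polyherit
Title: Heredity Indices and Recurrence Risk under a Polygenic
    Liability-Threshold Model
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates Mendelian transmission of additive polygenic
    liabilities between first-degree relatives, computes expected
    relative-proband correlations for dichotomized (threshold) traits both
    by simulation and by an analytic bivariate-normal quadrant-probability
    oracle, and estimates the heredity indices HIC (continuous traits,
    observed parent-offspring correlation over the Mendelian expectation
    of 0.5) and HIB (binary traits, observed phi correlation over the
    expected correlation at the trait's prevalence). Includes a
    recurrence-risk calculator conditioning on one first-degree
    relative's affection status and a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
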