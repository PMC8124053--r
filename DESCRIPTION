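Package: nepscore
Title: Prognostic Scoring and Survival Stratification for Stage IV
    Entero-Pancreatic Neuroendocrine Neoplasms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes the NEP point-based prognostic score for stage IV
    well-differentiated entero-pancreatic neuroendocrine neoplasms, both in
    its end-of-follow-up form (NEP-T) and its diagnosis-time form (NEP-D),
    together with the Delta-NEP difference and low/intermediate/high risk
    classes.  Evaluates score thresholds against vital status with confusion
    matrices, diagnostic accuracy metrics and chi-square association tests,
    scans candidate cutpoints by Youden's J and related policies, and
    reconstructs published 2x2 tables from cohort margins and group death
    percentages.  Provides Kaplan-Meier survival curves, log-rank
    comparisons, mean overall survival and five-year survival counts for
    score-defined strata, cohort CSV reading with per-row validation, a
    Table-style cohort summary, and a synthetic-cohort simulator with
    configurable marginal frequencies and a score-linked exponential hazard
    so every downstream analysis is testable without patient-level data.
License: MIT
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
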