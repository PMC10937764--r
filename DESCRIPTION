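Package: stonecea
Title: Decision-Tree Cost-Effectiveness Analysis for Acute Ureteric Stone Management
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for single-episode decision-tree cost-effectiveness
    analysis of acute ureteric stone treatment strategies, comparing
    emergency ureteroscopic laser fragmentation (EUL) against emergency
    stenting followed by delayed ureteroscopy (DUL). Provides a
    parameterised decision-tree engine with expected-value rollback and a
    path-enumeration oracle, calibration of free branch probabilities and
    episode costs to published cost totals, incremental
    cost-effectiveness ratios (ICER, cost per inpatient-day averted) with
    dominance handling, deterministic one-way and joint plus/minus 10
    percent sensitivity analysis (tornado and box-vertex ranges),
    two-arm cohort comparison statistics (pooled two-proportion z tests
    and summary-statistic t tests), NHS reference-cost table handling,
    and a synthetic two-arm patient-cohort generator with parameter
    re-estimation for end-to-end checks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
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
    tibble,
    withr,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
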