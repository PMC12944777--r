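Package: ruleout
Title: Evaluating AI Rule-Out Thresholds for Screening Programs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A statistical framework for choosing and auditing "rule-out"
    (triage) thresholds when an AI risk score is used to exclude low-risk
    screening exams from radiologist review. Provides stratified error
    accounting at any threshold (caseload reduction rate; gross, net, and
    adjusted-net false omission rates; false discovery rate; predictive
    values), threshold sweeps over a score grid, two threshold-selection
    policies (Youden's J and the adjusted-net-false-omission-zero rule),
    percentile bootstrap confidence bands for the error curves, and a
    synthetic screening-cohort simulator with closed-form expected metrics
    for validation. Includes a command-line interface for running sweeps,
    selections, bootstraps, and simulations from CSV input.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    jsonlite,
    optparse,
    readr,
    rlang,
    stats,
    tibble,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
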