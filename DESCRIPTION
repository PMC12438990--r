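Package: diagtraj
Title: Diagnostic Trajectory Sequence Analysis for Child and Adolescent
    Psychiatric Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying diagnostic trajectories after a first
    psychiatric diagnosis in childhood or adolescence, using registry-style
    dated ICD-10 event records. Maps ICD-10 F-codes to 19 analysis
    categories, builds 10-period annual diagnostic state sequences with
    last-diagnosis-per-window assignment and prevailing-diagnosis
    projection, computes normalized sequence entropy and group contrasts,
    summarizes diagnostic shifts with small-cell suppression, and
    estimates time-to-subsequent-diagnosis hazard ratios with
    Bonferroni-adjusted confidence intervals. A discrete-time Markov
    cohort simulator with known ground truth makes every pipeline stage
    testable without access to the original registers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    tibble,
    purrr,
    readr,
    rlang,
    lubridate,
    ggplot2,
    jsonlite,
    yaml,
    survival,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
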