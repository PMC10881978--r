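Package: screencea
Title: Cost-Effectiveness Analysis of AI-Based Diabetic Retinopathy Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools to study the trade-off between diagnostic accuracy and
    long-run cost-effectiveness of artificial-intelligence graders in diabetic
    retinopathy (DR) screening programmes. Generates synthetic screened cohorts
    of per-image five-grade (R0, R1, R2, R3s, R3a) probability vectors, sweeps
    a grade-level decision-threshold grid to derive 1100 receiver-operating
    points, runs each operating point through a hybrid decision-tree plus
    Markov cohort model of annual screening over 30 one-year cycles, and ranks
    scenarios by incremental cost-effectiveness ratio and net monetary benefit
    with dominance and extended-dominance frontier logic, tornado-style
    univariate sensitivity analysis, probabilistic sensitivity analysis with
    cost-effectiveness acceptability curves, and prevalence-by-willingness-to-
    pay grids.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
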