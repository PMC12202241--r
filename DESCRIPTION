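Package: trialcea
Title: Trial-Based Cost-Effectiveness Analysis with Seemingly Unrelated
    Regression and Bootstrapped Acceptability Curves
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for economic evaluation alongside two-arm randomized
    trials: quality-adjusted life years from EQ-5D-5L utilities or EQ-VAS,
    reliable-change classification on the BSI-18 Global Severity Index,
    resource-use costing under societal and payer perspectives including
    human-capital productivity costs, covariate-adjusted incremental
    cost-effectiveness ratios via Zellner seemingly-unrelated-regression
    feasible GLS, bias-corrected accelerated bootstrap intervals,
    cost-effectiveness planes and net-benefit acceptability curves, plus a
    seeded synthetic two-arm trial generator so the entire pipeline can be
    exercised without access to trial data.
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
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
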