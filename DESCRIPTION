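Package: ceaclust
Title: Within-Trial Cost-Utility Analysis for Cluster Randomised Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for within-trial cost-utility analysis of cluster
    randomised trials: EQ-5D-3L tariff valuation of health states,
    quality-adjusted life-years (QALYs) as the area under the utility
    curve with a death rule and NICE-style annual discounting, unit-cost
    based costing of resource use from healthcare and societal
    perspectives including intervention training and delivery costs,
    multiple imputation by chained equations with predictive mean
    matching, cluster-adjusted incremental cost and QALY estimation by
    random-intercept regression, bias-corrected bootstrap inference
    pooled across imputations, and decision outputs (incremental
    cost-effectiveness ratios, cost-effectiveness planes and
    acceptability curves, net monetary benefit). A synthetic-data module
    generates cluster-trial datasets with missing-at-random missingness
    so the full pipeline is testable without access to trial data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    lme4,
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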