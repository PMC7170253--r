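Package: pps20
Title: Multi-Cohort Prognostic Gene Signature Discovery and the PPS20
    Pancreatic Cancer Score
Version: 0.1.0
Authors@R:
    person("pps20", "Maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: A pipeline for discovering and validating prognostic gene
    expression signatures across multiple survival cohorts, built around
    the 20-gene pancreatic ductal adenocarcinoma score (PPS20).
    Implements per-gene univariate Cox proportional-hazards screening
    with rank aggregation of p-values and folded hazard ratios
    ("ranksum"), top-K cross-cohort intersection with tuning-cohort
    retesting, signed-sum score construction with median
    dichotomization, Kaplan-Meier/log-rank and multivariate Cox
    (backward Wald) validation, adapters for previously published
    comparator signatures including cross-platform cut-off transfer, and
    a cell-line drug-sensitivity correlation screen. Ships a
    negative-binomial/exponential-hazard synthetic cohort generator with
    planted prognostic genes so the whole pipeline is testable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    stats,
    survival,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
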