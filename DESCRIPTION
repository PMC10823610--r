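Package: strokecea
Title: Decision-Tree and Markov Cohort Cost-Effectiveness Modelling for
    Acute Ischemic Stroke Cytoprotective Therapy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A lifetime cost-effectiveness pipeline for comparing
    cytoprotective treatments of acute ischemic stroke: a 90-day decision
    tree chained to a 40-year modified-Rankin-Scale state-transition
    (Markov cohort) model with discounted cost and QALY accrual, ICER and
    net-monetary-benefit comparison, one-way deterministic and
    probabilistic sensitivity analysis, and an unanchored
    matching-adjusted indirect comparison (MAIC) stage with a synthetic
    individual-patient-data generator for end-to-end rehearsal. Ships a
    fully parameterised Chinese healthcare-system base case (2021 CNY)
    comparing edaravone dexborneol with human urinary kallidinogenase.
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
    rlang,
    stats,
    tibble,
    tidyr,
    yaml
Suggests:
    jsonlite,
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
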