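Package: radcea
Title: Markov Cohort Cost-Effectiveness Analysis for Radiotherapy Strategies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A decision-analytic pipeline for comparing radiotherapy strategies
    (intensity-modulated radiotherapy versus three-dimensional conformal
    radiotherapy in head-and-neck cancer) from a societal perspective. Provides
    bottom-up micro-costing with human-capital indirect costs and currency
    conversion, EQ-5D-3L utility scoring against pluggable time-trade-off value
    sets, a cohort Markov engine over toxicity-defined health states with
    discounting and half-cycle correction, incremental cost-effectiveness
    ranking with strict and extended dominance, deterministic (tornado) and
    probabilistic (Monte Carlo, acceptability curve) sensitivity analysis, and
    a synthetic-data module that emulates the study-shaped inputs with known
    ground truth.
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
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
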