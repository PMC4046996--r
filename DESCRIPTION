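Package: alarmcea
Title: Cost-Effectiveness Modelling of Smoke Alarm Promotion in
    Households with Pre-School Children
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A probabilistic decision-analytic model for comparing
    interventions that promote functioning smoke alarms in households
    with children under five. Combines a one-off intervention decision
    tree, a five-year pre-school Markov cohort model of fire-related
    injury, and a lifetime (ages 5-99) Markov projection of the
    consequences of severe injury, all discounted to birth. Includes a
    seedable probabilistic sensitivity engine driven by declarative
    parameter distributions and a correlated effectiveness posterior,
    incremental cost-effectiveness analysis with dominance and extended
    dominance, cost-effectiveness acceptability curves, expected value
    of perfect information, scenario (one-way sensitivity) analyses and
    cost-perspective filters, plus a fully synthetic parameter fixture
    so the whole pipeline runs self-contained.
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
    MASS,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
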