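Package: mhealthcea
Title: Forecasted Cost-Effectiveness of Scaling Up a National mHealth
    Maternal and Child Health Program
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested, configurable pipeline for forecasting the incremental
    cost-effectiveness of scaling a combined maternal-messaging and
    frontline-worker data mHealth program (the MOTECH model) across Ghana's
    districts. Covers synthetic generation of district registries and
    exit-interview records, propensity-score nearest-neighbour estimation of
    treatment effects on service coverage, ingredients-based costing with a
    phased three-year rollout, coverage projection with breakpoint
    attenuation, a transparent attributable-risk lives-saved engine with
    discounted years-of-life-lost DALYs, incremental cost-effectiveness
    ratios against GDP-multiple thresholds, and one-way and probabilistic
    sensitivity analyses with cost-effectiveness planes and acceptability
    curves.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ggplot2,
    jsonlite,
    stats,
    tibble,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
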