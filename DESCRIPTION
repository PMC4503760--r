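Package: ltecon
Title: Twenty-Year Economic Forecasting of Liver Transplantation Demand and Costs
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A deterministic cohort model of the United States liver
    transplantation system over a 20-year horizon (2014-2033). Forecasts
    waitlist demand stratified by MELD (Model for End-Stage Liver Disease)
    score, waitlist attrition, transplant and 10-year post-transplant
    survival, and discounted per-patient treatment costs across the
    pre-transplant, hospital-admission and post-transplant phases, with
    cost escalation and present-value discounting. Includes probabilistic
    sensitivity analysis (Monte Carlo over triangular and uniform parameter
    distributions) with certainty-to-base summaries and contribution-to-
    variance sensitivity indices, a catalog-price cost calculator for
    bioengineering autologous liver grafts from iPSC-derived cells, and a
    synthetic-scenario generator for property testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
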