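Package: frailmap
Title: Small-Area Frailty Estimation and Vaccination Equity Ratios
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Scores survey respondents on a deficit-accumulation frailty
    index, fits a weighted proportional-odds ordinal regression of frailty
    category on age band, sex and area deprivation quintile (with multiple
    imputation by chained equations and Rubin pooling), post-stratifies the
    predicted category probabilities onto area age-sex population tables to
    estimate expected frail and pre-frail counts per area with parametric
    bootstrap confidence intervals, and computes dose-per-person equity
    ratios for vaccination roll-outs (doses per frail person, per older
    person, and per risk-factor diagnosis), including extreme-ratio factors
    and quintile heatmap tables. A synthetic-data generator with a known
    generative model and a Monte-Carlo oracle makes the whole pipeline
    testable without access to restricted survey microdata.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
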