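Package: dividendsim
Title: Two-Scenario Demographic Dividend Macro-Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A single-age, two-sex cohort-component population projection
    engine with a goalpost-driven scenario layer for estimating the first
    demographic dividend. Builds per-sex life tables from a target life
    expectancy via a Brass logit relational model, disaggregates five-year
    census age groups to single ages with Beers ordinary multipliers,
    projects populations annually from fertility (TFR plus a normalized age
    distribution of births), mortality, sex ratio at birth and optional net
    migration, and compares scenarios through dependency ratios, the
    demographic window of opportunity, labour-force and service
    requirements, and GDP per capita. Includes a synthetic-data generator
    producing India-like high-fertility base pyramids and scenario anchor
    bundles so the whole pipeline runs without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
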