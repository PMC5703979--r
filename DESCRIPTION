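Package: oxmod
Title: Oxidant-Gas Modification of PM2.5-Mortality Associations in Survival Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how the combined oxidant capacity (Ox) of
    nitrogen dioxide and ozone modifies the association between long-term
    fine particulate matter (PM2.5) exposure and mortality in population
    cohorts. Provides a synthetic cohort generator with calibrated pollutant
    surfaces, exposure assembly (redox-weighted Ox, lagged moving averages
    updated for residential mobility, year adjustment, exclusion rules,
    reporting increments), stratified Cox proportional-hazards analyses
    (single-pollutant, two-pollutant, product-term, tertile and joint-tertile
    models), and a joint nonlinear concentration-response model in which a
    hinge threshold in Ox modifies the shape-constrained PM2.5 risk function,
    estimated by profile likelihood over the threshold and shape parameters
    with bootstrap uncertainty.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    survival,
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
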