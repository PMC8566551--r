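Package: amphipheno
Title: Predicting Amphibian Spring Migration Onset from Plant Phenology
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects amphibian spring-migration events in citizen-science
    sighting records using spatial, temporal and quantitative criteria,
    reduces flagged observations and plant phenophase reports to regional
    onset dates (day of year per taxon, climatic region and year), and fits
    robust MM-regression models that predict the onset of common frog and
    common toad migration from plant flowering and leaf-unfolding dates,
    including lag forecasts with 95% confidence intervals. Ships a synthetic
    data generator with known ground-truth onsets and lags so the whole
    pipeline is testable without access to the original sighting databases,
    plus trend (Mann-Kendall), correlation and model-validation (LOOCV,
    Cook's distance, VIF) tooling.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    geosphere,
    tibble,
    dplyr,
    readr,
    rlang,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
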