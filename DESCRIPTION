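Package: swpclim
Title: Modeling and Climatic Standardization of Grapevine Stem Water Potential
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for separating the effects of soil water availability and
    climatic conditions on grapevine stem water potential (SWP). Derives daily
    climatic covariates (maximum vapor pressure deficit, FAO-56 Penman-Monteith
    reference evapotranspiration, growing degree days) from station weather
    records, fits a family of five nonlinear SWP models driven by predawn leaf
    water potential, maximum air temperature or VPD, and seasonality, compares
    them by AIC/BIC/RMSE with leave-one-plot-out cross-validation, and
    standardizes measured SWP values to reference climatic conditions by
    algebraic inversion of the fitted models. Includes a synthetic field-study
    generator (weather seasons, plot-level predawn water potential trajectories,
    paired consecutive-day observations) for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    jsonlite,
    rlang,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
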