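Package: sapflux
Title: Heat-Pulse Sap Flow Processing and Microclimate-Driven Prediction
    for Cacao Agroforestry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Processes Heat Ratio Method (HRM) heat-pulse sensor data into
    heat-pulse velocity and volumetric sap flow, derives vapor pressure
    deficit and hourly microclimate summaries from under-canopy weather
    records, and fits a linear mixed model predicting cacao sap flow from
    air humidity, air temperature, photosynthetically active radiation and
    vapor pressure deficit with system-specific intercepts and slopes for
    three agroforestry shade arrangements.  Includes a seedable synthetic
    campaign generator calibrated to bundled reference microclimate and
    coefficient tables, goodness-of-fit statistics (RMSE, percent bias,
    Nash-Sutcliffe efficiency, observed-versus-predicted regression), and
    nocturnal reverse-flow summaries for hydraulic-redistribution
    detection.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    stats,
    utils,
    graphics,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
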