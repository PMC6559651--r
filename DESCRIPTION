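Package: oysterHSI
Title: Habitat Suitability Index Modelling for Intertidal Rock Oysters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to build, apply and verify a habitat suitability index
    (HSI) model for intertidal reef-forming oysters in monsoon-dominated
    coastal waters. The pipeline aggregates station survey data into monsoon
    and non-monsoon seasonal means, transforms seven environmental variables
    (temperature, salinity, dissolved oxygen, pH, chlorophyll-a, particulate
    inorganic matter, flow velocity) through piecewise-linear suitability
    curves, combines them into life-stage component indices by geometric
    means, maps station scores onto a coastline by nearest-neighbour
    interpolation, and verifies model output against oyster population
    descriptors (density, shell height, condition index) with bootstrap
    correlations and forward-stepwise regression. A synthetic-data generator
    reproduces the statistical structure of an 80-station monsoon-coast
    survey so that every stage is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    geosphere,
    jsonlite,
    yaml,
    car,
    nortest
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
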