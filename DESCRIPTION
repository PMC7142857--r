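Package: tmaexposure
Title: Dynamic Time-Microenvironment-Activity Population Exposure Modelling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for urban population exposure assessment with a dynamic
    time-microenvironment-activity (TMA) model resolved by mode of transport.
    Converts hourly gridded pollutant concentration fields, land-use polygons
    with residential population, tagged transport-network polylines, diurnal
    activity profiles, modal splits and outdoor-to-indoor infiltration factors
    into per-cell, per-microenvironment total exposure and population-weighted
    exposure. Includes top-down disaggregation of gridded annual road-transport
    emissions to road-link line sources, zero-out source-contribution
    accounting, emission and infiltration sensitivity scenarios, standard air
    quality model evaluation statistics (MB, NMB, RMSE, r, IOA, FAC2), and a
    seeded synthetic-city generator so the whole pipeline runs self-contained.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    tibble,
    tidyr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
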