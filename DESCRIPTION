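Package: phenosense
Title: Data Pathway for Ground-Based Micro-Climate and Phenology Sensor Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for managing data from ground-based ecological sensor
    deployments (phenology towers and understory wireless networks): parsing
    and validating heterogeneous data-logger exports with full defect
    accounting, timestamp quality assurance by comparing observed and
    expected sunrise times, physical-range checks and midday/clear-sky
    filtering, aggregation with coverage rules, derivation of broadband
    vegetation indices (NDVI, EVI2), leaf area index, vapour pressure
    deficit and sensor footprint geometry, and inverse-distance-weighted
    spatial fields with co-registered reliability maps. A seeded synthetic
    deployment generator emulates diurnal irradiance, micro-climate cycles,
    sensor failures, clock shifts and format corruptions so the whole
    pipeline is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    rlang,
    tibble,
    tidyr,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
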