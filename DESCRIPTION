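Package: n2oiso
Title: Chamber N2O Fluxes, Isotopocule Source Partitioning and Soil Water Diagnostics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Processing chain for automatic-chamber nitrous oxide measurements
    with laser-spectroscopic isotopocule analysis. Estimates areal N2O fluxes
    from closed-chamber headspace time series by linear regression with an R2
    acceptance gate, derives microbial source signatures (d15N-alpha, d15N-beta,
    d18O, site preference, bulk d15N) from Keeling-plot intercepts with quality
    classification, partitions emissions between the denitrification group and
    nitrification by Monte-Carlo two-endmember mixing with a Rayleigh correction
    for partial N2O reduction, converts soil-moisture sensor records to
    water-filled pore space with neighbor-plot gap filling and threshold
    day-count diagnostics, and evaluates daily biogeochemical-model output
    against observed cumulative fluxes (RMSE, pathway splits, Welch monthly
    weather comparison). A synthetic-data generator emulates every input so the
    whole chain is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
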