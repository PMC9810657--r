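Package: coastalghg
Title: Sea-Air CO2 and CH4 Fluxes and Greenhouse-Gas Budgets for Coastal
    Habitats
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for computing sea-air greenhouse-gas fluxes from
    equilibrator and cavity ring-down spectrometer (CRDS) measurements of
    dissolved CO2 and CH4 in shallow coastal waters.  Implements gas
    solubility (Bunsen coefficient and volumetric solubility), Schmidt
    numbers with brackish-water interpolation, a quadratic wind-speed gas
    transfer velocity, and the bulk sea-air flux equation; quality control
    of raw water/air measurement cycles (transition purging, interval
    averaging, diel composites, daily integration); seasonal and annual
    flux budgets with error propagation and CO2-equivalent CH4 accounting
    via the sustained-flux global warming potential; one-way ANOVA and
    Tukey HSD comparisons computed from group summary statistics; oxygen
    penetration depth from sediment microprofiles; and a seeded synthetic
    campaign generator with a ground-truth ledger for end-to-end pipeline
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    lubridate,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
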