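Package: urbancanopy
Title: Heat Vulnerability Indexing and Tree-Planting Prioritization for
    Urban Census Tracts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Builds a census-tract Heat Vulnerability Index (HVI) from
    sociodemographic and land-cover indicators using varimax-rotated
    principal components weighting, standard-deviation band scoring (1-6)
    and component summation; aggregates block-group land cover to tracts
    to measure existing and potential ('plantable') tree canopy; combines
    vulnerability, summer land surface temperature and planting
    feasibility into per-tract priority flags with intervention
    recommendations; and filters an approved tree-species table by site
    constraints, flagging species with high heat-reduction potential.
    Ships seed-deterministic synthetic generators for every input (tract
    variables from a latent-factor model, block-group land cover, land
    surface temperature, tract geometries) plus a command-line interface,
    so the full pipeline runs and is testable without any external data
    download.
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
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
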