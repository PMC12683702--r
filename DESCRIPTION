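Package: reefstates
Title: Coupled Coral-Macroalgae Dynamics and Management Scenarios on Reef Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates benthic cover dynamics (coral, macroalgae, free space)
    on networks of reefs coupled by larval and gamete dispersal, where each
    reef can be locally bistable between coral- and macroalgal-dominated
    states depending on herbivore grazing. Provides a synthetic seascape
    generator with distance-decay dispersal kernels, translation of survey
    covariates (herbivore density, sedimentation) into per-reef grazing and
    coral mortality rates, a management-intervention engine (fishery-closure
    expansion, water-quality improvement, and their combination), network
    summary metrics including healthy-reef counts and net larval migration,
    an expected-value-of-perfect-information (EVPI) decision analysis over
    grazing-rate uncertainty, and factorial sensitivity grids over mortality,
    overgrowth, dispersal range, and initial conditions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    geosphere,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
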