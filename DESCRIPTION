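Package: gridmodules
Title: Self-Organization of Grid-Cell Modules in Coupled Continuous
    Attractor Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a stack of two-dimensional continuous attractor
    networks modeling the rodent medial entorhinal cortex, in which a
    dorso-ventrally increasing inhibition distance combined with excitatory
    coupling between neighboring networks self-organizes the population
    activity into discrete grid modules. Provides the full analysis chain
    for simulated recordings: spatial rate maps, autocorrelograms, grid
    scale, orientation and gridness scoring, module clustering, and
    classification of commensurate, discommensurate, incommensurate and
    defect lattice relationships between adjacent modules. Includes
    synthetic rodent trajectory generation, perturbation and lesion
    protocols, two-network excitation-inhibition phase sweeps, and
    ensemble statistics of module scale ratios.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
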