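Package: cfreserve
Title: Counterfactual Protected-Area Network Design with Connectivity and
    Genetic Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Compares proactive (high development risk) and expedient (low
    risk, "high and far") strategies for siting protected areas on seeded
    synthetic forest landscapes.  Provides a simulated-annealing reserve
    selector with selection-frequency ranking in the MARXAN idiom,
    forest-loss-driven updates of landscape resistance and above-ground
    biomass carbon, resistant-kernel connectivity surfaces with
    FRAGSTATS-style patch metrics, validation of loss-probability rasters
    (AUC, sensitivity, specificity, kappa-optimal cut-point), and a
    spatially explicit individual-based simulation of mating, dispersal
    and genetic drift for a forest carnivore.  A single seeded pipeline
    reproduces the full seven-scenario comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    EBImage,
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    e1071,
    jsonlite,
    yaml,
    withr
Config/testthat/edition: 3
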