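Package: benthicFe
Title: Reaction-Transport Modelling of Sediment Iron Diagenesis with
    Stable Isotope Tracking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A one-dimensional steady-state reaction-transport model of
    early iron diagenesis in marine sediments that tracks the 56Fe/54Fe
    composition of every iron pool. The model couples organic-matter
    mineralization (multi-G), iron-oxide reactivity classes, iron-sulfide
    and pyrite formation, bioturbation (biodiffusive mixing and non-local
    bio-irrigation) and molecular diffusion, and computes benthic
    dissolved-iron fluxes and their delta-56Fe signature. Includes
    bioturbation scenario experiments over bottom-water oxygen gradients,
    calibration of effective isotope fractionation factors against
    measured profiles, predictive transfer functions for the magnitude
    and isotopic signature of the benthic iron flux, and depth-interval
    global upscaling.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    deSolve,
    Matrix,
    minpack.lm,
    stats,
    utils,
    graphics,
    grDevices,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
LinkingTo:
    Rcpp
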