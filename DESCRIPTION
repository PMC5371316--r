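Package: helixscan
Title: Helix Propensity Scanning of Disordered Protein Segments by
    Restrained Coarse-Grained Sampling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates per-segment helix propensity of intrinsically
    disordered protein regions with a coarse-grained Calpha helix-coil
    model: umbrella sampling restrained on a distance-RMSD (dRMSD)
    reaction coordinate with Hamiltonian replica exchange, WHAM
    reconstruction of free-energy profiles and helical-state populations,
    structural-ensemble statistics (geometric helicity, radius of
    gyration, contact counts, Daura clustering, force-field-variant
    dominance analysis), and secondary-structure propensity (SSP) from
    NMR Calpha/Cbeta secondary chemical shifts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    tidyr,
    purrr,
    tibble,
    ggplot2,
    rlang,
    jsonlite,
    generics,
    bio3d,
    seqinr,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
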