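Package: tdcsfield
Title: Finite-Volume Simulation of Transcranial Direct Current Stimulation in Voxel Phantoms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quasi-static volume-conductor modelling of transcranial direct
    current stimulation (tDCS). Builds parametric layered-sphere head and
    simplified whole-body voxel phantoms, places clinical pad/sponge electrode
    montages at 10-20 scalp positions or extracephalic sites, solves the
    Laplace equation for heterogeneous conductivity with a finite-volume
    discretization and a preconditioned conjugate-gradient solver, and derives
    electric field and current density normalized to the injected current.
    Includes a multilayer-sphere analytic series oracle for solver
    verification, focality volume metrics (V70/V50), per-tissue descriptive
    statistics, coefficient-of-variability dosimetry in decibels, and
    rank-based nonparametric tests (Kruskal-Wallis, Mann-Whitney with exact
    small-sample p-values, Bonferroni adjustment).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    Rcpp,
    RNifti,
    jsonlite,
    methods,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
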