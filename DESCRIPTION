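Package: tesdose
Title: Voxel Finite-Element Dosimetry for Transcranial Electrical Stimulation
Version: 0.1.0
Authors@R: person("Aaken", "Replication Team", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Forward modelling of transcranial electrical stimulation (tES)
    dose on voxelized head models. Generates synthetic multi-shell head
    phantoms with sex- and region-dependent skull water content, maps
    MRI-like T1/T2/PD intensity volumes to tissue resistivity, solves the
    quasi-static current-flow (Laplace) problem with a trilinear hexahedral
    finite-element method and preconditioned conjugate gradients, samples
    mean current density in a 10 mm spherical cortical target under 10-20
    electrode sites, and fits mixed-effects ANOVA models of log current
    density across electrode configurations, sites, intensities and sex.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    lme4,
    igraph,
    jsonlite,
    methods,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
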