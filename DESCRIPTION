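Package: fgmem
Title: Finsler-Geometry Monte Carlo Simulation of Two-Component Lipid
    Membranes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Dynamically triangulated surface Monte Carlo simulation of
    phase separation in two-component (liquid-ordered / liquid-disordered)
    lipid membranes.  Each triangle of a closed fluid surface carries a
    binary phase label; the Hamiltonian couples an Ising-like aggregation
    (line tension) energy to Gaussian and bending energies whose effective
    surface tension and bending rigidity depend on the local phase through
    a Finsler metric.  Provides mesh construction and topology-safe bond
    flips, exact local Metropolis energy differences, move-radius
    auto-tuning, shape and domain-morphology observables, phase-plane
    scans, and PLY/OFF snapshot export.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    igraph,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
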