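Package: rbfekit
Title: Toy-Scale Alchemical Relative Binding Free Energy Calculations
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Desk-scale machinery for alchemical relative binding free energy
    (RBFE) workflows on analytically solvable model systems. Implements
    multisite lambda dynamics with adaptive landscape flattening and
    population-based free energies, windowed free energy perturbation with
    Bennett acceptance ratio (BAR) estimation, a charge-renormalized
    multiple-topology ligand model with exact maximum common substructure
    search, thermodynamic-cycle composition with neutral-intermediate routing
    for net-charge perturbations, forward/reverse convergence diagnostics, and
    protocol cost accounting. Every estimator can be validated against closed
    forms because the model systems are one-dimensional harmonic wells with
    exact free energies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
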