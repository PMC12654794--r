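Package: rarmd
Title: Replica-Averaged Restrained Coarse-Grained Molecular Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Ensemble-averaged experimental restraints for coarse-grained
    (C-alpha trace) polypeptide molecular dynamics. Implements flat-bottom
    distance and virtual-bond-angle penalty potentials with analytic
    gradients, inverse-power replica averaging with scheduled full and
    partial updates, force scaling, multiplexed temperature replica
    exchange, NVE and Langevin integrators over a pluggable surrogate
    potential, NOE-style violation metrics (rho-u-plus, satisfied
    percentages, violation counts), state-population analysis, Ward
    clustering of ensembles into representative families, and a synthetic
    two-state benchmark generator for validating that replica averaging
    recovers multi-state ensembles that single-conformation restraining
    cannot.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    bio3d,
    stats,
    utils,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
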