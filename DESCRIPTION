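Package: mdcm
Title: Minimal Distance Constraint Model and Stability/Flexibility Analysis
    of Protein Conformational Ensembles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Implements the minimal Distance Constraint Model (mDCM) for
    all-atom protein structures and conformational ensembles: constraint
    network construction (covalent bonds, Mayo-style hydrogen bonds and salt
    bridges, backbone torsions), a (6,6) body-bar pebble game for network
    rigidity, Monte Carlo sampling of constraint topologies over the
    (N_hb, N_nat) macrostate grid, free energy landscapes and heat capacity
    curves with parameter fitting to a target melting transition, and
    Quantitative Stability/Flexibility Relationship (QSFR) metrics
    (Flexibility Index, Cooperativity Correlation). Includes ensemble
    reduction by centroid clustering on pairwise RMSD, cluster-weighted
    averaging over representative structures, Z-score comparative statistics
    for paired variant systems, hydrogen-bond propensity tables, RMSF
    mobility profiles, and a synthetic peptide/ensemble generator so the
    whole pipeline runs without external structure files.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    bio3d,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
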