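Package: hydronet
Title: Neural Prediction of Protein Hydration Thermodynamics from Static Structures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for predicting the converged thermodynamic hydration state
    of protein binding sites (water occupancy and desolvation free energy on a
    3D grid) directly from a static structure.  Implements physics-based
    molecular interaction fields for a configurable probe library, per-point
    descriptors with spherical-harmonics environment encodings, 3D U-Net
    semantic segmentation of occupancy levels trained with a generalized Dice
    loss, point-wise classifier and regressor networks, quality-threshold and
    density-based clustering of occupancy grids into discrete hydration sites,
    and desolvation-based scoring of ligand series for structure-activity
    analysis.  A synthetic-data module generates toy binding pockets with
    oracle hydration grids so the full pipeline can be exercised and validated
    without molecular-dynamics input.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    bio3d,
    cluster,
    pracma,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    ChemmineR,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
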