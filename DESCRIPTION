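Package: tcrcost
Title: Structure Correction and Binding Prediction for TCR-Peptide Complexes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for working with predicted three-dimensional structures of
    CDR3A:CDR3B:peptide complexes. Implements a structure-correction network
    that refines low-quality predicted coordinates by processing main-chain
    and side-chain atoms separately under three geometric training losses
    (a frame-aligned point error on backbone frames, a distance-difference
    loss over side-chain atom pairs, and a peptide-bond geometry penalty),
    and a residual 3D convolutional classifier that predicts TCR-peptide
    binding from voxelized atom features. Includes PDB structure input and
    output, per-atom chemical featurization, voxelization on a 1 Angstrom
    lattice, peptide-swap negative sampling, classification metrics, and a
    deterministic synthetic-complex generator for offline testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
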