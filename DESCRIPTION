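Package: scmomtf
Title: Interpretable Multitask Learning for Paired Single-Cell Multi-Omics Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Joint analysis of paired single-cell multi-omics data (RNA+ATAC or
    RNA+ADT) with a single shallow multitask network: an adversarial
    autoencoder produces a low-dimensional cell embedding (dimension
    reduction), a label-smoothed softmax head classifies cell types, and the
    encoder-decoder pair doubles as a least-squares-GAN generator for data
    simulation. Includes batch correction by reference-batch training,
    sampling-based Shapley feature attribution with ATAC peak-to-gene mapping,
    chance-adjusted clustering metrics (ARI, NMI, AMI), and a seeded synthetic
    paired-omics generator with planted cell types, marker features, rare
    populations and batch effects.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Matrix,
    data.table,
    jsonlite,
    stats,
    utils,
    graphics,
    methods,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
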