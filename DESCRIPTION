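Package: hepamorph
Title: 3D Morphometry of Hepatic Vasculature and Steatosis in Whole-Liver Volumes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Voxel-level analysis of whole-liver bright-field (Nissl) volumes
    for fibrosis phenotyping: seeded region growing of vein trees, sinusoid
    extraction by thresholding with vessel subtraction, topology-preserving 3D
    skeletonization with per-point diameter estimation, the standard vessel
    morphometry panel (mean diameter, length density, segment count, volume
    fraction), a trainable voxel classifier standing in for cloud deep-learning
    steatosis segmentation, Euclidean-distance-transform perivascular band
    quantification, and label-analysis-style per-component shape statistics.  Ships a
    synthetic phantom generator with exact ground truth (branching vein trees,
    a sinusoid mesh, pericentral steatosis with a programmed distance-decay
    profile) so the full pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    igraph,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
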