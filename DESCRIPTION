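Package: danioscape
Title: Pigment Pattern Morphospace, Cell Metrics, and Backcross Mapping for Danio Fishes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of striped and spotted pigment patterns in
    Danio fishes. Provides local-threshold (Sauvola) segmentation of
    melanophores and xanthophores from flank images, a pattern morphospace
    based on dorsoventral and anteroposterior variation of binarized
    melanized elements, nearest-neighbour and density statistics of pigment
    cells, rigid registration and frame linking of daily image series to
    quantify melanophore movement, and backcross genetics: single-QTL LOD
    scans by Haley-Knott regression with permutation thresholds and 1.5-LOD
    support intervals, two-locus epistasis analysis, and extreme-phenotype
    F_ST scans. Includes seeded generators for ground-truthed synthetic
    pattern images, developmental image series, and backcross families so
    every stage of the pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    Rcpp,
    EBImage,
    igraph,
    png
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
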