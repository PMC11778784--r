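Package: cardiomorph
Title: Multi-Layer Tissue Segmentation and 3D Morphometry of Tubular Organs
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Contour-based segmentation of multi-channel fluorescence
    z-stacks into tissue layers and an integrated 3D morphometric suite for
    tubular organs such as the embryonic zebrafish heart. Per-slice contours
    are classified as internal or external by containment parity and
    combined with boolean mask algebra (XOR/AND) to build per-channel tissue
    masks and to recover, label-free, the extracellular-matrix compartment
    enclosed between two tissue layers. Binary masks are triangulated into
    watertight surfaces in physical coordinates; lumen centrelines are
    extracted by maximal-inscribed-sphere pathfinding on the distance
    transform; and looping ratios, chamber partitions, bounding-ellipsoid
    geometry, ballooning and wall-thickness vertex maps, standardized 2D
    unrolled heatmaps with cross-specimen averaging, and internuclear
    distance cell statistics are computed on top. Synthetic phantoms with
    closed-form ground truth support validation end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    tools,
    tiff,
    jsonlite,
    EBImage,
    FNN,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
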