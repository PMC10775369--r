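Package: cycmif
Title: Cyclic Multiplexed Immunofluorescence Registration, Segmentation and
    Single-Cell Profiling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: End-to-end analysis of cyclic multiplexed immunofluorescence
    (mIF) image stacks. Groups raw stain/quench image pairs by field of view,
    cycle and channel; subtracts quenched backgrounds, normalizes by
    intensity percentiles and denoises; estimates per-cycle rigid
    translations by trial-averaged masked cross-correlation on
    maximum-projected, downsampled images; segments individual immune cells
    with a three-class (background / interior / boundary) U-Net trained
    under a composite loss combining weighted cross-entropy, soft per-class
    Jaccard, cell-count and auto-encoding penalties; aggregates per-cell
    marker intensities, removes outliers, calls marker positivity and
    assigns immune phenotypes from a marker-combination rule table; and
    discovers cell subpopulations by UMAP embedding and hierarchical
    density-based clustering. A fully ground-truthed synthetic-data
    generator makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    EBImage,
    tiff,
    jsonlite,
    yaml,
    uwot,
    S4Vectors,
    SummarizedExperiment
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    mclust,
    cluster,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
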