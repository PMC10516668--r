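Package: crispa
Title: Colony-Array Pigment Screen Analysis with Synthetic Plate Benchmarks
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for arrayed colony screens that read out a
    pigment phenotype from plate images: grid segmentation and HSV-based
    yellowness scoring of 384/1536-format colony arrays, frame-median edge
    correction and screen z-normalization, iterative Grubbs replicate
    filtering, gene-level aggregation across pooled screens, yellow/white/cyan
    hit-group calling, hypergeometric hit-overlap and reproducibility
    statistics, and over-representation analysis rendered as a shared-gene
    term graph. A seeded synthetic-screen generator (layouts with
    quadruplicate position randomization, planted pigment and fitness effects,
    plate and edge biases, contamination) renders plate images with known
    ground truth so every stage of the pipeline is verifiable end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    tools,
    EBImage,
    png,
    tiff,
    igraph,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'utils.R'
    'synthgen.R'
    'render.R'
    'imgquant.R'
    'platecorr.R'
    'screenstats.R'
    'enrichgraph.R'
    'io.R'
    'pipeline.R'
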