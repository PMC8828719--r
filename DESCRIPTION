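Package: TiledContacts
Title: Analysis of Tiled Capture-C Chromatin Contact Matrices
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for targeted chromosome-conformation-capture (Tiled-C)
    contact matrices over a single tiled genomic region: sparse triplet
    matrix input/output on a fixed bin grid, iterative correction (ICE)
    balancing, scaling of samples to a common total, replicate merging and
    subtraction matrices, virtual Capture-C viewpoint profiles, intra-TAD
    insulation ratios, boundary CTCF contact and enhancer-promoter contact
    quantification, and a nonparametric statistical layer (Kruskal-Wallis
    with Dunn's post hoc comparisons and Holm or Benjamini-Hochberg
    adjustment). A generative model of tiled contact maps with distance
    decay, nested domains and loop anchors supplies fully synthetic data
    emulating a developmental time course and boundary-knockout variants,
    so the complete analysis is exercisable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    DESeq2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
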