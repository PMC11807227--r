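Package: revent
Title: Reverse-Degree Topological Indices, Edge-Weight Entropies and QSPR
    Models for Molecular Graphs
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Computes reverse-degree based topological indices (Randic,
    atom-bond connectivity, geometric-arithmetic, Zagreb-type, forgotten,
    augmented Zagreb, Balaban-type, redefined Zagreb, harmonic, symmetric
    division degree, inverse-sum-indeg) and Shannon-type edge-weight and
    vertex-information entropy measures on simple connected molecular
    graphs. Supports parameterized edge-partition families whose class
    counts are affine in a polymer repeat parameter, with exact affine
    closed forms for every index, and ships the hyaluronic
    acid-paclitaxel conjugate partition as a built-in fixture. Includes a
    QSPR regression harness (ordinary least squares, ridge, lasso,
    elastic net, support vector regression) relating molecular
    descriptors to physicochemical drug properties, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    igraph,
    glmnet,
    e1071
Suggests:
    testthat (>= 3.0.0),
    ChemmineR,
    ChemmineOB,
    jsonlite,
    withr,
    MASS
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
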