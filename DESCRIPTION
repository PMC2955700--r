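Package: fragnet
Title: Layout Optimization for Fragmented Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-stage layout optimization for networks that split into many
    unconnected components, as common in gene, protein-interaction and other
    biological similarity networks. Each component is laid out internally with
    the Fruchterman-Reingold force-directed algorithm; the components are then
    placed and rotated as rigid bodies so that their proximity reflects a
    user-supplied vertex dissimilarity matrix, either by an exact semi-physical
    spring simulation or by a fast approximation that combines SMACOF
    multidimensional scaling of component-level distances with a simulated
    annealing rotation phase. Includes the evaluation toolkit
    (layout-distance Pearson correlation, fragmentation threshold sweeps,
    nearest-component similarity overlays), synthetic instance generators with
    planted ground truth, TSV/Pajek network input, and SVG rendering.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    xml2
Config/testthat/edition: 3
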