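Package: spatlas
Title: Spatial Transcriptomic Atlas Construction: Cell Typing, Tissue
    Regions, Imputation and Viral Tropism
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building annotated atlases from targeted in situ
    transcriptomic measurements of tissue. Implements amplicon-level
    quality control and barcode-to-cell assignment, cell and gene
    filtering with normalization and location-scale batch correction,
    reference-based consensus cell-type label transfer over joint
    embeddings, molecular tissue-region segmentation from spatial-niche
    expression with label post-processing, leave-one-gene-out tuned
    mutual-nearest-neighbour gene imputation, Delaunay cell-cell
    adjacency analysis, and per-group viral-barcode tropism summaries.
    A synthetic-data generator with full ground truth makes every stage
    verifiable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    RANN,
    deldir,
    igraph,
    irlba,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    mclust,
    interp,
    sva,
    withr
Config/testthat/edition: 3
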