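Package: tilfrc
Title: TIL-FRC Microenvironment Analysis for Imaging Mass Cytometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the fibroblastic reticular cell (FRC) network and
    CD8+ tumour-infiltrating lymphocyte (TIL) compartment of lymph-node
    imaging-mass-cytometry cores. Classifies stromal pixels into FRC, LEC
    and BEC compartments, measures reticular-network morphometry (skeleton
    branches, gap radii, fibre shape), phenotypes CD8+ TILs by graph-based
    community detection on checkpoint and granzyme-B markers, groups
    samples into TIL-FRC environments (TFEs) by hierarchical clustering of
    z-scored cluster frequencies, profiles cell-to-network distances, and
    stratifies overall survival by TFE. Includes a seeded synthetic-data
    generator emulating the statistical structure of a lymphoma tissue
    microarray so the whole pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    cluster,
    dplyr,
    EBImage,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    Matrix,
    purrr,
    readr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    tiff,
    tools,
    utils,
    withr,
    yaml
Suggests:
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
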