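Package: voltphen
Title: Electrical Immunophenotyping of Innate Immune Cells from Cyclic Voltammetry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Label-free classification of THP-1 monocytes, dendritic cells and
    macrophages from cyclic-voltammetry (CV) measurements of cell suspensions.
    Implements double-layer capacitance extraction from CV current traces
    (i = C dv/dt), validity masking near sweep vertices, media de-embedding by
    pointwise division, peak-time concentration analysis, and size-ordering
    classification driven by the proportionality between membrane capacitance
    and cell surface area. Ships an equivalent-circuit suspension simulator and
    a synthetic-micrograph generator with exact ground truth, plus an imaging
    arm (Otsu segmentation, per-cell area measurement) that provides the
    independent verification of the electrical size ordering.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    png,
    purrr,
    rlang,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
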