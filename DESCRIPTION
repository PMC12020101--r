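Package: ldscreen
Title: High-Content Lipid Droplet Screening: Simulation, Segmentation and
    Robust Hit Calling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for high-content drug-repurposing screens that
    read out lipid droplet burden in patient fibroblasts. Provides a synthetic
    plate and microscopy-field generator with exact ground truth, seeded
    segmentation of nuclei, cells and intracellular puncta, per-object
    morphometry (area, Crofton perimeter, compactness, form factor) aggregated
    into per-well screen parameters, Z-prime plate quality control, robust
    SD-distance (sample-median z) scoring of compounds, four-parameter
    intersection hit calling, and normality-gated two-group organelle
    comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    readr,
    jsonlite,
    yaml,
    igraph,
    EBImage,
    tiff,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown,
    optparse
Config/testthat/edition: 3
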