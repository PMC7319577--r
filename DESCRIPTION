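Package: chemprobe
Title: Normalization and Analysis of Low-Throughput RNA Chemical Probing Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing capillary-electrophoresis RNA chemical
    probing experiments (SHAPE, DMS and CMCT). Reads QuShape tab-separated
    output and pre-normalized reactivity files, applies the standard
    top-10-percent/exclude-20-percent outlier-trimmed normalization with
    probe-specific nucleotide subsets, averages replicates, drives external
    probing-directed and sequence-only secondary-structure prediction
    engines, computes a base-pair consensus over predictions, renders
    reactivity heatmaps and barplots, exports VARNA colour maps, and maps
    reactivities onto the B-factor field of PDB structures for 3D
    visualization.
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
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    bio3d,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
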