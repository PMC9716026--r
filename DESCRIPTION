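Package: itfprofiler
Title: Invasive-Tumor-Front Profiling from Histology, Immunofluorescence
    and DNA Methylation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantitative characterisation of the invasive tumor front (ITF).
    Segments reticulin fibers from Gomori silver-stained histology tiles and
    computes a fifteen-parameter morphometric suite (including a dispersion
    index, "deformity", normalised so a disk scores 1), tiles 5 x 4 mm regions
    of interest into 1 x 1 mm categories (tumor, target tissue, ITF), detects
    and phenotypes immune cells in multiplex immunofluorescence images (DAPI,
    CD3, CD8, CD20, CD68, CD66b) reporting densities in cells per square
    millimetre, and runs an Infinium-style per-CpG differential-methylation
    stage (beta values, Greedycut filtering, probe-type quantile
    normalisation, per-CpG linear models with Benjamini-Hochberg FDR, CpG
    island/shore/shelf context annotation, signature clustering and PCA).
    A seeded synthetic-data generator reproduces the statistical structure of
    every input so the full pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    generics,
    withr,
    jsonlite,
    yaml,
    tiff,
    EBImage,
    GenomicRanges,
    IRanges,
    S4Vectors,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
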