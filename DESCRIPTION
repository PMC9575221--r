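Package: ccibench
Title: Benchmarking Cell-Cell Interaction Predictions with Spatial Transcriptomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Evaluates ligand-receptor based cell-cell interaction (CCI)
    predictions from single-cell RNA-seq tools by integrating matched spatial
    transcriptomics. Ligand-receptor pairs are classified into short-, medium-
    and long-range interactions with an entropic-regularized optimal-transport
    (Sinkhorn) statistic and a permutation test; cell-type pairs are classified
    into near, medium and far by k-means on mean nearest-spot distances; tool
    outputs are scored with a GSEA-style Distance Enrichment Score and with
    precision/recall/F1 against consensus or simulated ground truth. Includes a
    semi-synthetic simulator that plants spatially consistent ligand-receptor
    signals in paired scRNA-seq and spatial data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Matrix,
    dplyr,
    purrr,
    tibble,
    rlang,
    readr,
    ggplot2,
    generics,
    jsonlite,
    pracma,
    methods,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
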