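Package: binetminer
Title: Dense Bipartite Sub-Network Mining for Tumor-Stroma Co-Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mines weighted bipartite gene co-expression networks built from
    matched tumor and stroma expression profiles for dense bipartite
    sub-networks (BiNets) with a provable lower bound on output density.
    Implements the full pipeline: simulation of paired-tissue expression data
    with planted cross-tissue modules and survival outcomes, median-matched
    normalization and low-variation filtering, Pearson-correlation bipartite
    graph construction, greedy seed-and-grow component mining with a
    size-dependent admission schedule and an analytic density guarantee,
    density-thresholded agglomerative merging of BiNets into macro networks
    with a dendrogram, and survival-based biomarker evaluation by city-block
    K-means patient stratification and log-rank testing.
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
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    ape,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
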