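Package: plaquenet
Title: Co-Expression Modules, Eigengene Bayesian Networks and Regulator
    Prioritization for Unstable Atherosclerotic Plaque
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A multi-stage network pipeline for two-group transcriptomic
    cohorts such as stable versus unstable atherosclerotic plaque: weighted
    gene co-expression analysis (soft-thresholded adjacency, topological
    overlap, module detection and eigengene merging), module-level gene-set
    overrepresentation with cluster enrichment scores, gene set enrichment
    on the fold-change ranking, Bayesian network structure learning over
    module eigengenes with bootstrap arc strengths, consensus transcription
    factor prioritization from tree-ensemble and mutual-information
    regulatory networks intersected with motif support, module proximity
    statistics, expression-matched signature scoring, and connectivity-score
    drug repurposing. Ships a synthetic-data generator with known ground
    truth for end-to-end validation.
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
    jsonlite,
    purrr,
    ranger,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    fgsea,
    mclust,
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
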