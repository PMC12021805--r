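Package: pdsgraph
Title: Explainable Graph-Transformer Classification of Parkinsonian
    Syndromes from Regional Radiomics Similarity Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Builds per-subject metabolic brain networks from regional
    radiomic feature tables using the Regional Radiomics Similarity
    Network (R2SN) approach (collinearity pruning, per-subject min-max
    normalization, inter-regional Pearson correlation over a 96-region
    atlas), classifies subjects into idiopathic Parkinson's disease,
    multiple system atrophy and progressive supranuclear palsy with a
    graph-transformer whose multi-head attention is masked by
    connectivity strength, and explains predictions through
    gradient-based node importance and attention-based edge importance.
    Includes a supervised-contrastive composite training objective, a
    two-stage pretrain/fine-tune protocol, a synthetic cohort generator
    with planted disease signatures for end-to-end validation,
    per-class evaluation utilities and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    tools,
    tibble,
    dplyr,
    tidyr,
    purrr,
    readr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    yaml,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
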