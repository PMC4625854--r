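Package: pdblood
Title: Blood Transcriptomics of Early Parkinson's Disease: Classification,
    Differential Expression, Enrichment and Drug-Network Queries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for case/control analysis of whole-blood expression
    profiles from drug-naive Parkinson's disease cohorts. Implements a
    chemometric classification chain (PLS-DA variable preselection,
    Ranking-PCA discriminant variable ranking, linear discriminant
    analysis with forward selection of principal components and
    non-error-rate diagnostics), three differential-expression procedures
    (a SAM-style moderated statistic with permutation FDR, the Rank
    Product permutation test, and a normal-theory probability of positive
    log ratio), gene-level signature intersection, Fisher/EASE term
    enrichment with Benjamini-Hochberg adjustment, preranked GSEA
    enrichment scores, a GSEA-based drug-network similarity query with
    community enrichment, and RT-qPCR reference-gene selection (geNorm,
    NormFinder) with relative quantification. A synthetic-data module
    generates two-class cohorts, qPCR plates and drug networks with
    planted structure so the whole pipeline is testable without external
    data.
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
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
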