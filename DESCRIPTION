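Package: wntbn
Title: Discrete Bayesian Network Analysis of Wnt Pathway Epigenetics in
    Colorectal Cancer
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds and analyses discrete Bayesian network models of the Wnt
    signaling pathway in colorectal cancer. Three fixed network topologies
    (with and without prior biological knowledge and epigenetic nodes for
    promoter methylation and histone marks) are parameterized from fixed
    literature-derived priors and from gene expression training data via
    median discretization, class/methylation cross-tabulation, a tunable
    transcription-complex effect weight, and pseudo-count smoothing. Exact
    posterior inference (variable elimination, with a brute-force enumeration
    oracle), an exhaustive leave-pair-out holdout experiment testing whether
    the beta-catenin/TCF4 transcription-complex state tracks tumor status,
    ROC/AUC and two-sample Kolmogorov-Smirnov evaluation, and an ancestral
    sampling generator for synthetic labeled cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    pROC,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
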