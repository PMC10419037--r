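Package: demandscope
Title: Topic and Sentiment Mining of Short Health-Community Comments
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Mines information demands and emotions from corpora of short
    user comments, such as those posted in online health communities.
    Provides collapsed-Gibbs latent Dirichlet allocation with perplexity
    and UMass-coherence model selection, embedding-refined topic vectors
    and fused document representations, a rule-based sentiment calculus
    over a polarity/intensity emotion lexicon (7 major categories, 21
    subcategories), primary-topic classification with category
    aggregation, topic-emotion Pearson correlation analysis, a
    cross-validation evaluation harness, and a synthetic corpus generator
    with planted ground truth so every stage is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
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
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
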