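Package: readrank
Title: Understandability Estimation and Understandability-Aware Ranking for
    Health Web Pages
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates how understandable health-related Web pages are for the
    general public, and integrates those estimates into document ranking.
    Implements HTML text extraction under naive and boilerplate-removal
    pipelines with sentence-ending heuristics, eight traditional readability
    formulae with their raw components, medical-vocabulary and natural-language
    feature extractors, corpus-derived word-frequency rank features, latent
    semantic estimators trained on difficulty-graded background corpora, BM25
    retrieval with top-k reranking, reciprocal rank fusion and learning to
    rank, and understandability-aware evaluation measures from the rank-biased
    precision family (uRBP, RBP_r, RBP_u, MM_RBP, condensed variants and
    residuals). A seeded synthetic-fixture generator produces corpora, pages
    and judgments so the whole pipeline runs self-contained.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    xml2,
    jsonlite,
    xgboost,
    e1071,
    nnet,
    randomForest
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
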