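Package: smcc
Title: Semi-Supervised Multi-Label Collective Classification on
    Attributed Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Predicts multi-label node classes (e.g. protein functions) on
    partially labeled attributed networks with a generative model: a pLSA
    likelihood over node attribute counts, regularized by symmetric
    Kullback-Leibler smoothness over network edges and over correlated
    labels, fitted by an EM algorithm with labeled nodes clamped to their
    known labels. Includes an ensemble variant over constructed latent
    graphs (even-step random walk with restart, prediction-similarity kNN),
    largest-gap relevant-label extraction, multi-label ranking metrics
    (coverage, ranking loss, macro-F1), and a synthetic generator for
    homophilous, correlated multi-label networks.
License: MIT
Encoding: UTF-8
Imports:
    Matrix,
    glmnet,
    methods,
    stats,
    utils
Suggests:
    e1071,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
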