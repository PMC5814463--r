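Package: sepsig
Title: Gene-Expression Prognostic Signatures for Sepsis Mortality
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for building and evaluating whole-blood gene-expression
    prognostic scores for 30-day sepsis mortality across many cohorts.
    Implements the parameter-free difference-of-geometric-means signature
    score, re-trainable penalized logistic regression and random forest
    predictors with cross-cohort feature selection, trapezoidal AUROC and
    AUPRC, Kester-Buntinx summary ROC curves, continuous net reclassification
    improvement against clinical severity scores, ensemble and consensus
    analyses, gene-set over-representation with background filtering, and a
    synthetic multi-cohort expression simulator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    limma,
    glmnet,
    randomForest,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
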