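Package: cxrnlp
Title: Natural Language Processing of Pediatric Chest Radiograph Reports
    for Pneumonia
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to classify free-text pediatric chest radiograph (CXR)
    reports as positive or negative for pneumonia. Provides corpus
    input/output and cohort construction (inclusion filtering,
    per-encounter deduplication, disposition-stratified
    derivation/validation splitting, dual-annotator adjudication), a
    keyword lexicon with negation expansion and phrase-count
    featurization, an unsupervised skip-gram word-embedding classifier
    scored by cosine similarity against reference phrases, five
    supervised classifiers (depth-wise and leaf-wise gradient boosted
    trees, linear-kernel support vector machine, Gaussian naive Bayes,
    L2-penalized logistic regression), diagnostic-accuracy statistics
    with exact and log-method confidence intervals, Cohen's kappa, a
    synthetic report-corpus generator for fully reproducible testing,
    and a command-line pipeline tying the stages together.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
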