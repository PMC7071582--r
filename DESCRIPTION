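Package: dtscore
Title: Druggability Scoring of Proteins by Positive-Unlabeled Random Forest Bagging
Version: 0.1.0
Authors@R:
    person("dtscore", "developers", email = "dtscore@example.org", role = c("aut", "cre"))
Description: Scores human proteins by their similarity to approved drug targets.
    Builds a unified protein feature matrix (sequence-derived annotations,
    tissue-specificity entropy of expression profiles, protein-protein
    interaction network centralities, and rank-based ontology enrichment
    scores), then trains a bagged ensemble of balanced random-forest
    classifiers on approved-drug targets versus repeatedly sampled
    pseudo-negatives (positive-unlabeled learning). Outputs per-protein
    druggability probabilities, averaged mean-decrease-Gini feature
    importances, and ROC/cross-validation evaluation reports. Includes a
    synthetic-data generator with controllable effect sizes so the full
    pipeline is testable without external databases, plus a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
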