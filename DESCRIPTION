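Package: ppiforest
Title: Sequence-Only Protein-Protein Interaction Prediction from Domain
    Pair Odds and Subcellular Localization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Predicts whole-genome physical protein-protein interaction
    (PPI) networks from sequence-derived features alone: pairwise PFAM
    domain log-of-odds scores learned from experimentally verified
    interactions, domain-domain interaction evidence, and subcellular
    localization features, combined in a random-forest classifier.
    Includes downstream network analyses of the predicted interactome:
    functional-similarity evaluation (pathway sharing, information-content
    ontology semantic similarity, co-expression enrichment) against
    degree-preserving randomized networks, significant metabolic
    pathway-pathway linkage detection with Markov clustering and
    annotation enrichment, disease-disease association networks scored by
    literature co-occurrence, and logistic-regression tests of duplicate
    gene retention after whole-genome duplication. A synthetic-data
    generator with planted signal makes the full pipeline testable
    without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    randomForest,
    igraph,
    stats,
    utils,
    parallel
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
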