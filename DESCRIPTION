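Package: tlmnet
Title: Telomere Length Maintenance Gene Classification and Discovery in Yeast
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An interpretable machine-learning pipeline for telomere length
    maintenance (TLM) genetics in budding and fission yeast. Builds feature
    tables from genetic-interaction profiles against pathways and GO terms,
    protein-complex membership indicators, and random-walk-with-restart
    proximity to anchor genes on a protein-protein interaction network;
    resolves one-to-one orthologs by Smith-Waterman local alignment and
    quantifies cross-species phenotype conservation; evaluates classifiers
    with repeated stratified cross-validation (Matthews correlation
    coefficient and ROC AUC, median-aggregated); ranks novel TLM candidates
    by leave-one-out prediction and tests them for gene-set
    overrepresentation with Fisher's exact test and Benjamini-Hochberg
    correction. A synthetic-world generator with planted TLM structure makes
    every stage testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    Biostrings,
    glmnet,
    jsonlite,
    stats,
    utils,
    tools,
    methods,
    withr
Suggests:
    testthat (>= 3.0.0),
    xgboost,
    randomForest,
    ranger,
    e1071,
    pROC
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
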