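Package: neuralpcos
Title: Random-Forest and Neural-Network Derived Diagnostic Scoring for
    Two-Class Gene Expression Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Builds a gene-expression diagnostic score for a two-class
    condition (case/control, e.g. polycystic ovary syndrome versus
    normal) from microarray or RNA-seq data. The pipeline screens
    differentially expressed genes with a moderated t-statistic,
    characterises them by hypergeometric term enrichment with
    redundancy pruning, selects marker genes by random-forest Gini
    importance, derives per-gene weights from a small feed-forward
    neural network, and combines them into a linear 'neuralPCOS' score
    evaluated by ROC/AUC. A synthetic-data module generates two-class,
    multi-batch expression matrices with planted differential signal so
    every stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    randomForest,
    sva,
    jsonlite,
    yaml,
    fgsea
Suggests:
    testthat (>= 3.0.0),
    limma,
    pROC,
    withr,
    knitr
Config/testthat/edition: 3
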