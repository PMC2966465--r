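Package: metaroc
Title: ROC-Based Metagene Classification of Two-Class Expression Data
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Univariate gene-expression-average ("metagene") classification
    for two-class phenotypes. Genes are ranked by oriented AUC
    (max(AUC, 1-AUC)) computed from the Mann-Whitney rank statistic, the
    top-ranked genes are averaged into a single sign-corrected metagene, and
    a decision threshold is fitted by maximizing training accuracy. Includes
    leave-one-out cross-validation with in-fold feature selection, balanced
    accuracy, signature-size sweeps, gene-transfer external validation,
    null-AUC diagnostics on randomized data, expression-matrix preprocessing
    (duplicate-gene merging, k-nearest-neighbour imputation, mean centring,
    quantile normalization), and a synthetic two-class data generator with
    planted differential genes.
License: GPL (>= 2)
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    limma,
    stats,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
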