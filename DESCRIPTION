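Package: lfqpipe
Title: Label-Free Proteomics Differential Abundance and Biomarker Modeling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An end-to-end workflow for label-free quantification (LFQ)
    proteomics intensity data: parsing of MaxQuant 'proteinGroups.txt'
    tables and generic intensity matrices, quality filtering
    (contaminant/reverse/site decoys, unique-peptide and group-wise
    missingness rules), left-censored MinProb imputation, quantile
    normalization, empirical-Bayes moderated t-tests with
    Benjamini-Hochberg correction, and construction and evaluation of
    classifier panels from top differential proteins (correlation
    pruning, stratified splitting, repeated cross-validation, ROC/AUC).
    Includes a ground-truth synthetic LFQ data generator and a
    publication-style figure suite with plain-text data exports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    caret,
    dplyr,
    e1071,
    generics,
    ggplot2,
    grDevices,
    jsonlite,
    kernlab,
    limma,
    randomForest,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    xgboost
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
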