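Package: m6apred
Title: Sequence-Based Prediction of N6-Methyladenosine Sites with
    Dinucleotide Features and Gradient Boosting
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts N6-methyladenosine (m6A) sites from fixed-length RNA
    sequence windows centered on a candidate adenosine. Sequences are encoded
    with two positional descriptors (dinucleotide binary encoding and local
    position-specific dinucleotide frequency), features are ranked by the
    two-class F-score and pruned by sequential forward search, and a
    gradient-boosted tree classifier is tuned by exhaustive grid search under
    stratified cross-validation. Includes the standard evaluation protocols of
    the field (pooled 10-fold cross-validation and jackknife; Sn, Sp, Acc,
    MCC, ROC/AUC), FASTA input with cleaning of irrelevant windows, a
    deterministic synthetic benchmark generator, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils,
    withr,
    xgboost
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
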