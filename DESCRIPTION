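Package: ctrepro
Title: Reproducibility Analysis for Plasma miRNA RT-qPCR Assays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates plasma microRNA RT-qPCR amplification curves with known
    ground truth, calls cycle-threshold (Ct) values under fixed or automatic
    per-target thresholds, computes delta-Ct relative quantification against an
    endogenous reference (RNU6) under fixed- and variable-threshold
    normalization, and runs a full reproducibility analysis suite:
    time-to-plasma-extraction decay, repeated sample acquisition,
    intra-operator (duplicate) and inter-operator variability, extraction
    method comparison, and a six-variant ANOVA family on delta-Ct with group,
    operator, interaction and threshold-covariate terms. Includes a screening
    statistics kernel: t-tests from printed summary statistics, chi-squared
    dropout tests, Benjamini-Hochberg FDR, FDR-adjusted per-test alpha for
    feature screening, detectable-effect power computation, and
    logistic-panel ROC/AUC.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    pROC,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
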