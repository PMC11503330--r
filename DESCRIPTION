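Package: pepforest
Title: Random-Forest Triage of Peptide-Array Antibody Signals for ELISA
    Validation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis of high-density tiled peptide-array serology screens.
    Computes per-peptide array features for a disease-versus-control
    contrast (signal fold difference, empirical-Bayes local false discovery
    rate by grid nonparametric maximum likelihood, effect-size r-values,
    whole-array threshold-crossing proportions, and nearest-neighbor
    averages over overlapping tiles), trains per-outcome random forests
    that predict whether a peptide's array signal will be confirmed by
    ELISA (Spearman correlation, fold change, rank-sum p-value), evaluates
    them by repeated 70/30 cross-validation, and selects candidate peptides
    by probability-threshold rules with modification-enrichment reporting.
    Includes a synthetic tiled-peptidome generator with planted epitopes
    and coupled ELISA measurements for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    randomForest,
    seqinr,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
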