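Package: lipidpanel
Title: Case-Control Lipidomics Biomarker Discovery with OPLS-DA and
    PCA-Weighted Diagnostic Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An end-to-end pipeline for discovering diagnostic lipid
    biomarker panels in case-control LC-MS lipidomics studies. Provides
    univariate case-control statistics (chi-square, summary-statistic Z,
    t and Mann-Whitney tests with a normality gate, Benjamini-Hochberg
    adjustment), from-scratch chemometrics (principal component analysis,
    Kaiser-Meyer-Olkin sampling adequacy, Bartlett's sphericity,
    orthogonal partial least squares discriminant analysis with variable
    importance in projection scores, stratified cross-validated Q2 and
    permutation validation), a three-criterion differential-lipid filter,
    PCA score-coefficient weighting that selects a compact diagnostic
    panel, composite-score ROC evaluation with DeLong confidence
    intervals, a lightweight transcriptome enrichment screen (batch
    adjustment, empirical-Bayes moderated t, preranked gene set
    enrichment, hypergeometric over-representation), and a synthetic
    case-control cohort generator so the whole pipeline is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    limma,
    pROC
Config/testthat/edition: 3
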