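Package: dmrev
Title: Reversal Biomarker Discovery from Paired Blood Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for paired (before/after intervention) bulk
    RNA-seq cohorts of myotonic dystrophy type 1 patients. Scores each
    patient's overall therapy response from a heterogeneous clinical outcome
    panel, associates per-gene expression with CTG-repeat length and with the
    compound response score via precision-weighted random-intercept linear
    mixed models with Satterthwaite degrees of freedom, and identifies
    reversal biomarkers: genes whose disease-associated dysregulation moves
    back toward normal levels in clinical responders. Includes a
    negative-binomial synthetic cohort generator with planted ground truth,
    a stratified patient-sampling emulation, and cross-study effect-size
    concordance against an external case/control cohort.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    lme4,
    lmerTest,
    limma,
    edgeR,
    jsonlite,
    withr
Config/testthat/edition: 3
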