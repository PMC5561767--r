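Package: sipwelm
Title: Self-Interacting Protein Prediction with Weighted Extreme Learning
    Machines on PSSM Local Average Group Features
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts self-interacting proteins (SIPs) from sequence
    evolutionary information. Position-specific scoring matrices (PSSMs)
    from PSI-BLAST are pooled into fixed-length 400-dimensional Local
    Average Group (LAG) feature vectors, optionally reduced by principal
    component analysis, and classified with a weighted extreme learning
    machine (WELM) whose per-class sample weights counter the strong
    SIP/non-SIP class imbalance. Includes explicit-feature and kernel WELM
    solvers, stratified cross-validation and holdout evaluation with
    confusion-matrix metrics and ROC/AUC, a synthetic PSSM generator for
    end-to-end testing, and a command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    pROC,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
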