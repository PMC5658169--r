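Package: offtargetr
Title: Bulge-Aware Alignment and Ensemble Prediction of CRISPR-Cas9 Cleavage Propensity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts the propensity of a genomic site to be cleaved by a
    given CRISPR-Cas9 single guide RNA (sgRNA). Implements a gap-budgeted
    Needleman-Wunsch alignment that tolerates up to three RNA/DNA bulges with
    a seven-window protospacer length search and PAM relocation; a feature
    registry spanning pairwise-similarity, mismatch-type, PAM, nucleotide
    composition, nearest-neighbor thermodynamic, DNA-shape and genomic
    annotation features; linear calibration of heterogeneous per-study read
    counts onto a common reference scale; class-imbalance-aware training of
    an ensemble of random-forest regressors over bootstrap-balanced datasets;
    leave-one-sgRNA-out and leave-study-out cross-validation with per-fold
    alignment-parameter re-optimization; greedy forward feature selection;
    and a synthetic-data generator with planted on/off-targets for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    ranger,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite,
    withr
Config/testthat/edition: 3
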