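Package: mirsurv
Title: Cross-Validated Prognostic miRNA Signatures for Survival Outcomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical workflow for developing and evaluating prognostic
    circulating-miRNA signatures from small-RNA-seq count data with
    censored survival outcomes. Covers unsupervised count filtering, TMM
    normalization and rank-based inverse-normal (Blom) transformation,
    elastic-net penalized Cox modelling with cross-validated penalty
    selection, out-of-fold prognostic indices with median-split
    cross-validated Kaplan-Meier curves, time-dependent ROC curves at a
    landmark timepoint with inverse-probability-of-censoring weights, and
    permutation tests of absolute and incremental predictive accuracy.
    Includes a synthetic-cohort generator so the full pipeline is testable
    without access to patient-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    edgeR,
    glmnet,
    jsonlite,
    stats,
    survival,
    utils,
    withr,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
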