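Package: ithsig
Title: Intratumor Heterogeneity Quadrants and Sampling-Bias-Aware
    Prognostic Signatures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies per-gene intratumor and intertumor expression
    heterogeneity from multiregion tumor cohorts, partitions genes into
    heterogeneity quadrants, audits prognostic gene signatures for
    multiregion sampling bias (discordant high/low risk calls across
    regions of one tumor), and builds survival signatures from genes
    that are stable within tumors but variable between patients via a
    univariate Cox screen, cross-validated penalized Cox refinement,
    and a multi-learner benchmark ranked by Harrell's concordance
    index.  Includes a synthetic multiregion cohort generator with
    known patient-level and region-level variance components and a
    planted proportional-hazards signature, plus survival evaluation
    utilities (Harrell's C, Kaplan-Meier/log-rank, multivariate Cox,
    inverse-probability-of-censoring-weighted time-dependent AUC, and
    fixed-effect hazard-ratio pooling with Cochran's Q and I-squared).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    ranger,
    stats,
    survival,
    utils,
    xgboost
Suggests:
    jsonlite,
    optparse,
    metafor,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
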