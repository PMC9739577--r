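Package: sigstrat
Title: Signature-Based Tumor Stratification and Survival Analysis
Version: 0.1.0
Authors@R:
    person("Sigstrat", "Developers", email = "sigstrat@example.org",
           role = c("aut", "cre"))
Description: Derives pathway-activity gene signatures from two-condition
    expression data by fold-change and significance filtering, classifies
    tumor samples by per-sample thresholded counting of signature genes with
    a Fisher exact test against the cohort average, stratifies patients into
    four retinoic-acid/ERK activity categories, and relates categories and
    stability-selected expression clusters to overall and relapse-free
    survival. Includes exact and rank-based statistical primitives,
    Kaplan-Meier and k-group log-rank machinery, bootstrap-Jaccard cluster
    stability selection, and a fully seeded synthetic cohort generator with
    planted truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    survival
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
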