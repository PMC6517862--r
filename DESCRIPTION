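Package: eaccd
Title: Prognostic Grouping of Cancer Survival Data by Ensemble Clustering
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds data-driven prognostic systems from patient-level
    cancer survival records. Combinations of prognostic factors (TNM
    stage components, dichotomized age, histology) are compared with a
    Gehan-Wilcoxon effect-size dissimilarity, refined by an ensemble of
    partitioning-around-medoids clusterings, and organized into a
    complete-linkage dendrogram. Dendrogram cuts are scored with
    Harrell's concordance index and the optimal number of prognostic
    groups is selected at the knee of the C-index curve subject to
    non-crossing Kaplan-Meier curves. Includes the AJCC 8th-edition
    staging rule for well-differentiated thyroid carcinoma, association
    and contingency analyses between groupings, a jackknife test for
    comparing concordance indices, and a synthetic SEER-like cohort
    generator with known latent risk structure for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    ape,
    cluster,
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
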