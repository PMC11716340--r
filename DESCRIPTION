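Package: rnaitier
Title: Target-Gene Prioritization for RNAi Lethality Screens
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for prioritizing insect pest-control target genes from
    genome-wide RNAi lethality screens. Scores per-cohort lethality with a
    technical-death exclusion rule, selects primary targets by a lethality
    threshold with a stricter cutoff for contaminated batches, assembles
    dose-response profiles from a validation screen with a high-dose
    imputation rule, tiers genes by k-means clustering of dose-response
    features (elbow-based k selection), tests annotation-term
    over-representation of the target set against a low-mortality background
    with the hypergeometric distribution, and evaluates cross-species
    transfer bioassays against a lethality-increase criterion. Ships a
    synthetic screen simulator with planted dose- and time-dependent potency
    tiers so every stage is testable with known ground truth.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
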