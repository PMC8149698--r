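Package: mirsens
Title: Analysis Pipeline for miRNA Drug-Sensitization Screens in HER2+ Breast Cancer Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements an end-to-end analysis pipeline for arrayed miRNA
    mimic/inhibitor viability screens combined with HER2-targeted drugs:
    per-plate loess spatial normalization and log2 transform, outlier-based
    sensitizer calling (median minus k standard deviations within a treatment
    group) with drug-independence and endogenous-expression exclusion
    criteria, multi-context candidate selection, validation-stage Student's
    t-tests against scrambled controls, lysate-microarray protein Z-score hit
    calling, Kruskal-Wallis differential miRNA expression across treatment
    arms, and clinical cohort association (Spearman miRNA-mRNA correlation
    with Benjamini-Hochberg control, pairwise Wilcoxon stage comparisons,
    median-split Kaplan-Meier survival with log-rank tests) plus local
    hypergeometric over-representation analysis on GMT gene sets. Ships
    seeded synthetic-data generators with ground truth for every input type
    so the whole pipeline is testable without laboratory data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    survival,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
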