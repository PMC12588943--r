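Package: segagree
Title: Inter-Observer Agreement Analysis for Tumour Segmentations on
    Intraoperative Ultrasound
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantifies how well multiple observers agree when segmenting
    tumour on 2-D intraoperative ultrasound stills. Computes pairwise Dice
    similarity coefficient (DSC) matrices across observers, factor-tagged
    group summaries by tumour type, operative stage and observer experience,
    per-pixel agreement heatmaps with colour banding and transparent overlay
    rendering, and the associated statistics (tie-corrected Kruskal-Wallis
    with Dunn's post hoc, Spearman rank correlation with exact permutation
    p-values at small n, two-way ANOVA with Tukey HSD). Includes a fully
    deterministic synthetic multi-rater study generator (phantom tumours,
    boundary-jitter rater model, difficulty ratings anticorrelated with
    agreement) so the entire pipeline is testable without clinical images,
    plus a single-command reporting pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    png,
    jsonlite,
    car,
    stats,
    utils,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
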