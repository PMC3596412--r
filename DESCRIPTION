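Package: slescore
Title: Leukocyte-Capture Antibody Microarray Analysis and Disease-Activity
    Scoring for Systemic Lupus Erythematosus
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for duplicate-spot leukocyte-capture antibody
    microarrays profiling peripheral blood mononuclear cells in systemic
    lupus erythematosus (SLE). Provides per-slide scale normalization to a
    0-10 expression range, replicate merging with low-expression and
    signal-to-noise quality filters, singleton biomarker screening by
    empirical-Bayes moderated t-statistics and tie-aware AUROC across six
    disease-activity comparisons, a support-vector-machine derived
    disease-activity S-score trained on class extremes (healthy and active
    SLE), repeated random sub-sampling cross-validation comparing array,
    conventional-laboratory and combined feature sets, and a seedable
    synthetic-cohort generator emulating the statistical structure of such
    studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    e1071,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    graphics
Suggests:
    testthat (>= 3.0.0),
    limma,
    optparse,
    withr
Config/testthat/edition: 3
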