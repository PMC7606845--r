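Package: dnbr
Title: Dynamic Network Biomarker Analysis of Stage-Ordered Expression Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects critical transition (tipping-point) stages in stage-ordered
    case/reference expression data with the dynamic network biomarker (DNB)
    composite index: per-stage mean absolute deviation from reference means
    (SD_in), mean absolute within-module Pearson correlation (PCC_in), mean
    absolute module-to-background correlation (PCC_out), and their composite
    CI = SD_in * PCC_in / PCC_out.  Provides a module search and an S3 model
    object with the detected critical stage, plus the supporting stages of a
    stage-wise biomarker workflow: Welch-t differential expression with
    Benjamini-Hochberg control, a lite weighted co-expression analysis
    (soft-threshold scale-free fit, topological overlap, module eigengenes,
    module-trait correlation), topological hub ranking of interaction networks
    with top-k consensus, tumor-suppressor overlap, a synthetic stage-ordered
    data generator with planted ground truth, and a deterministic pipeline
    orchestrator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
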