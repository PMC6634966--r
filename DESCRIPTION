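Package: damidseg
Title: DamID Tiling-Array Domain Calling and Regulatory Integration
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Processing and analysis of two-channel DamID tiling-array
    chromatin profiles: MA-style LOESS normalization with dye-swap
    correction, transition-based domain calling with a sliding edge
    filter, interval set comparison with fractional-overlap matching,
    empirical-Bayes moderated t-tests with Benjamini-Hochberg FDR for
    expression arrays, binding-by-regulation integration with
    hypergeometric overlap statistics, center-aligned meta-profiles,
    degenerate E-box motif enrichment against generated background
    sequence, and exact contingency and life-table statistics for
    phenotype assays. Includes a synthetic-data generator with planted
    ground truth for end-to-end validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    limma,
    Biostrings,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
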