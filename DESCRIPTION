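Package: nullchip
Title: Knockout-Calibrated ChIP-chip Target Calling and Expression
    Integration
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Calls transcription-factor target promoters from two-colour
    promoter tiling arrays using an empirical null significance threshold
    derived from knockout (protein-null) control hybridisations.
    Implements sliding-window median enrichment scoring, two-tier target
    curation with null-genotype cross-filtering, degenerate 8-mer motif
    over-representation scanning against a promoter background,
    litter-aware differential expression with a block-constrained
    genotype-label permutation test, integration of binding and expression
    evidence into direct and indirect target classes, and a synthetic-data
    generator with recorded ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    BiocGenerics,
    Biostrings,
    limma,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
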