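Package: mdcnet
Title: Modular Differential Connectivity Analysis of Gene Co-Expression Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds weighted gene co-expression networks (signed-hybrid
    adjacency, biweight midcorrelation, topological overlap) from bulk
    expression tables, detects co-expression modules, and tests each module
    for gain or loss of intra-modular connectivity between condition groups
    using the modular differential connectivity (MDC) ratio with a
    permutation null and Benjamini-Hochberg adjustment. Also provides module
    eigengene-behavior correlation, hub-gene selection by module membership
    and gene significance, one-tailed Fisher over-representation of custom
    gene categories against an expressed-gene background, nonparametric
    behavior-frequency comparisons, and a synthetic-data generator that
    emulates a stratified multi-region, multi-treatment animal study design
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    DESeq2,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
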