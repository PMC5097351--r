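Package: coexdiv
Title: Co-Expression Network Divergence of Duplicate Genes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Builds standardized Fisher Z-score gene co-expression networks
    from multi-tissue expression atlases and quantifies the regulatory
    divergence of duplicate gene pairs. Implements duplicate-pair detection
    from protein sequences, classification of duplication mode
    (whole-genome, tandem, inserted) from synteny, a six-type geometric
    classifier of co-expression neighborhood divergence, and tests of
    subgenome edge fractionation, module enrichment and hub-gene bias
    after whole-genome duplication. Ships a synthetic-data generator with
    planted modules, planted divergence types and planted subgenome
    structure so every stage can be validated against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    igraph,
    Matrix,
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
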