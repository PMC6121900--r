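Package: ptmgrav
Title: Posttranslational Modification Profiling of Proteins Accumulated in
    Spheroids Under Simulated Microgravity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for the in-silico stage of a two-condition label-free
    quantitation (LfQ) proteomics study of spheroid formation under simulated
    microgravity. Selects differentially accumulated proteins by a
    zero-baseline-or-fold-change rule with cross-cell-line concordance, parses
    and validates experimentally verified posttranslational modification (PTM)
    site records in a dbPTM-style flat format, normalizes modification names
    into canonical classes and residue-chemistry groups, materializes proteins,
    quantitation and classified sites as an RDF-style triple knowledge graph
    with basic-graph-pattern querying and N-Triples/Turtle serialization, and
    computes per-protein-per-class summary statistics. Includes a synthetic
    data generator with a planted ground-truth ledger so every stage is
    testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    tibble,
    dplyr,
    readr,
    rlang,
    yaml,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
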