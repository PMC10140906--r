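Package: pbmine
Title: Mining and Evolutionary Profiling of piggyBac Transposons
Version: 0.1.0
Authors@R:
    person("Riley", "Carter", email = "rcarter@example.org", role = c("aut", "cre"))
Description: Detects piggyBac (PB) DNA transposons in genome assemblies by
    translated homology seeding against a bundled transposase reference set,
    resolves element boundaries from terminal-inverted-repeat (TIR) pairs
    anchored by TTAA target-site duplications (TSDs), classifies copies as
    intact, full or truncated, censuses genomic copy numbers, builds family
    consensus sequences, computes Kimura 2-parameter divergence landscapes
    and invasion-age calls, and summarises clade structure with pairwise
    identity matrices, a neighbor-joining tree and TIR sequence logos.  A
    synthetic-genome simulator plants elements with known structure and
    divergence so every stage can be validated against a truth table.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    ape,
    jsonlite,
    methods,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
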