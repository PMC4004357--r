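Package: tsdcaller
Title: Split-Read Detection of De Novo Transposable Element Insertions
    via Target Site Duplications
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects de novo transposable element (TE) insertions from raw
    short reads by recognising the k-bp terminal sequences (head and tail)
    of a TE inside reads, extracting the genomic flank at each junction, and
    resolving insertion loci either reference-free by grouping flanks on
    their shared target site duplication (TSD) string, or by placing flanks
    uniquely on a reference genome, pairing head and tail junctions within a
    short window, and verifying the TSD against both flanks and the
    reference. Ships a seeded simulator (random genomes, planted insertions
    with TSDs in both orientations, paired-end reads with substitution
    errors) and truth-based evaluation, so the caller is fully testable
    offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
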