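Package: kogGC3
Title: Compositional Analysis of Coding Sequences by KOG Functional Category
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study synonymous (third codon position, GC3) base
    composition of coding sequences grouped into KOG functional classes and
    the three broad categories information storage and processing,
    cellular processes and signaling, and metabolism. Computes per-gene GC
    and GC3 from FASTA, applies the KOG class filters, transfers class
    labels across species via best-reciprocal-hit orthology, tests the
    Blue < Black < Red GC3 hierarchy with Mann-Whitney comparisons, runs a
    ternary-diagram (de Finetti) permutation test for the confinement of
    the metabolism category to the high-GC3 corner, produces butterfly-plot
    deviation tables with Bonferroni-corrected one-sample t-tests,
    quantifies GC3 increments between orthologous genomes, and associates
    functional classes with human chromosomal band types (L1+, L1-, H3-,
    H3+). A synthetic-data generator with planted per-class GC3 structure
    makes every stage testable without genome downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    Matrix,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
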