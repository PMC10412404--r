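Package: eadriver
Title: Driver Gene Detection in Laboratory-Evolved Bacteria Using
    Evolutionary Action Scores
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Identifies phenotype driver genes in adaptive laboratory
    evolution experiments on bacteria.  Variants from evolved strains
    (VCF, breseq GenomeDiff, or amino-acid substitution lists) are
    annotated against an annotated reference genome (GenBank or
    GFF3+FASTA), missense mutations are weighted by Evolutionary Action
    (EA) impact scores, and genes are ranked as candidate drivers by two
    EA-integration statistics (a one-sided Kolmogorov-Smirnov shift test
    and a Monte-Carlo sum test) alongside a length-normalized mutation
    frequency baseline.  Includes consensus overlap reporting across the
    three rankings, export of per-residue mutation-burden tracks onto
    protein structures for PyMOL, a deterministic synthetic-fixture
    generator, and a command-line interface.
License: MIT + file LICENSE
Depends:
    R (>= 4.1)
Imports:
    bio3d,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    rtracklayer,
    stats,
    tools,
    utils,
    vcfR,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
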