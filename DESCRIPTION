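Package: svarch
Title: Fine-Scale Architecture of Structural Variants from Paired-End
    Mapping Signatures
Version: 0.1.0
Authors@R:
    person("svarch", "developers", email = "svarch@example.org",
           role = c("aut", "cre"))
Description: Tools to simulate, classify and resolve the fine-scale
    architecture of structural variants (SVs) in inbred mouse strains.
    The package simulates multi-strain genomes carrying a catalog of 21
    paired-end mapping (PEM) signatures covering simple and complex SVs
    (deletions, insertions, inversions, tandem and dispersed gains, VNTRs
    and retrogene false positives), with realistic breakpoint
    micro-architecture (micro-insertions, micro-deletions,
    micro-homology, target-site duplications, poly(A) tails and SNPs
    co-segregating with the variant).  It classifies loci into the 21
    PEM patterns from read-pair orientation, insert-size and read-depth
    evidence, resolves breakpoints at nucleotide resolution from
    assembled locus sequences with outgroup-based ancestry inference,
    and provides a permutation test for SV overlap enrichment against
    genomic feature sets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    Rsamtools
Config/testthat/edition: 3
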