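Package: sdrscan
Title: Discovery of Sex-Determining Regions from Population Resequencing Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale pipeline for mapping a sex-determining region (SDR)
    from population resequencing genotypes and read-depth data. Implements
    per-site sex-association statistics (allelic Fisher's exact test, a
    binomial likelihood-ratio test on allele frequencies, Weir-Cockerham
    F_ST with genome-wide weighting, Benjamini-Hochberg FDR), detection of
    sex-specific SNPs by a heterozygosity-contrast rule with ZW/XY system
    classification, coverage-based calling of hemizygous (W- or Y-limited)
    regions by Welch's t-test with half-depth and absence criteria, assembly
    of sex-linked SNP clusters and hemizygous regions into an SDR with
    repeat-content summaries, variant annotation against gene models
    (coding-effect classification, UTR/intron/flank categories), and design
    of paralog-length-polymorphism PCR markers for genetic sexing via
    seed-and-extend alignment and in-silico PCR. A seeded synthetic-cohort
    generator produces a complete ZW (or XY) study -- reference genome, VCF,
    depth matrix, gene models, repeats, a planted haploid/diploid paralog
    pair and primers -- with a ground-truth record, so every stage is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vcfR,
    ape,
    Biostrings,
    IRanges,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    seqinr,
    withr,
    optparse
Config/testthat/edition: 3
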