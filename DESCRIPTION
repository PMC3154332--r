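Package: microsatMiner
Title: In Silico Mining of Polymorphic Microsatellites from
    Multi-Individual Transcriptome Assemblies
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects perfect di-, tri- and tetranucleotide
    microsatellites in assembled contigs, quantifies per-read repeat-unit
    counts from read-to-contig alignments to infer in silico allele number
    and variability, screens primer binding sites for SNPs, applies
    marker-selection filters (flanking sequence, coverage, annotation,
    isogroup redundancy), and provides the population-genetic validation
    statistics linking in silico variability to observed PCR polymorphism:
    observed/expected heterozygosity, exact and Monte-Carlo
    Hardy-Weinberg tests, Chakraborty null-allele frequencies, Fisher
    exact concordance testing, category summaries, and backward-deletion
    generalized linear models. A seeded read simulator emulating pooled
    multi-individual 454-style cDNA sequencing with repeat-slippage and
    substitution errors makes the whole pipeline testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomeInfoDb,
    GenomicRanges,
    Biostrings,
    Rsamtools,
    optparse,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
biocViews: Microsatellite, SequenceMatching, Alignment, Genetics,
    VariantDetection
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
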