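Package: mutaccum
Title: Mutation-Accumulation Rate Analysis Across Chromatin Domains
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates per-mitosis mutation rates from mutation accumulation
    (MA) experiments in haploid fungi and models their variation across the
    genome. Implements Bayesian Poisson rate models with exposure offsets,
    estimation of the number of mitoses per transfer from nuclei counts,
    mutation-rate models with GC-content and chromatin-domain predictors
    (H3K9me3, H3K27me3, centromeres), strand-collapsed single-nucleotide
    mutation spectra with nucleotide- and trinucleotide-frequency
    corrections, a flanking-base measurement-error regression, homopolymer
    slippage models for small indels, and windowed Watterson's theta with
    missing-data correction linked to predicted mutation rates. Includes a
    synthetic-data generator for chromatin-annotated genomes, MA mutation
    tables and population VCFs so every stage is testable without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    vcfR,
    jsonlite,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
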