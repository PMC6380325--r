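Package: phsdup
Title: Small Segmental Duplications from Pseudoheterozygous Sites in
    Haploid Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detection and population-genetic analysis of small segmental
    duplications from pseudoheterozygous sites (PHS) in haploid genome
    sequencing data. Apparently heterozygous sites in a haploid genome mark
    divergent positions between collapsed paralogous copies mapped onto a
    single reference locus. The package provides a quality-aware PHS caller,
    independent duplication evidence from split-read clusters and read-depth
    copy-number windows, qPCR copy-number estimation, merging of linked PHS
    into duplication calls with population frequencies,
    site-frequency-spectrum neutrality tests for singleton excess,
    permutation-based enrichment of duplications in annotated regions and
    functional-element tracks, Nei-Gojobori (1986) paralog dN/dS, and a
    calibrated synthetic-data generator emulating haploid-embryo resequencing
    for end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    IRanges,
    S4Vectors,
    GenomicRanges,
    Biostrings,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    VariantAnnotation,
    seqinr,
    withr
Config/testthat/edition: 3
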