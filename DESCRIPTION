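Package: pmdseq
Title: Sequence Determinants of Single-CpG Methylation in Partially
    Methylated Domains
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing single-CpG methylation levels inside
    partially methylated domains (PMDs) of whole-genome bisulfite
    sequencing data. Provides strand combining, CpG-island/DHS/SNP/coverage
    filtering and interval annotation; a positional dinucleotide linear
    model that predicts single-CpG methylation from the +-78 bp sequence
    environment, with coefficient-heatmap normalisation; allele-specific
    validation of dinucleotide effects from heterozygous SNPs flanking
    homozygous CpGs; identical-context pair correlation and
    distance-dependent spatial correlation analyses; MNase-seq nucleosome
    profiling around CpGs; and a fully specified synthetic-methylome
    generator with known ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    readr,
    stringr,
    rlang,
    ggplot2,
    generics,
    withr,
    Matrix,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    vcfR,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
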