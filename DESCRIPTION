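Package: pprcaps
Title: PPR Gene-Family Classification and SNP-to-CAPS Marker Design
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for genome-wide characterization of the pentatricopeptide
    repeat (PPR) gene family and for turning phenotype-associated SNPs into
    CAPS (cleaved amplified polymorphic sequence) markers. Detects tandem
    P/L/S and C-terminal E1/E2/E+/DYW motifs on protein sequences by
    log-odds profile scanning (or imported HMMER3 domain tables), assembles
    them into non-overlapping architectures, and assigns P/PLS subfamily
    and subgroup labels. Summarizes gene structure (intron counts,
    chromosomal distribution) from GFF3, estimates Ka/Ks for duplicated
    coding-sequence pairs by the Nei-Gojobori pathway method with
    Jukes-Cantor correction, filters genotype panels for
    phenotype-class-specific SNPs, converts SNPs to CAPS candidates by
    differential restriction-site scanning with fragment prediction, and
    scores marker-phenotype co-segregation (match rates). Includes a
    synthetic-data generator (proteins with planted motif architectures,
    multi-exon gene models, genotype panels with planted class-specific
    SNPs) so the whole pipeline is testable end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    withr,
    Biostrings,
    BiocGenerics,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    vcfR,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
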