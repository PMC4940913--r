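Package: tagtally
Title: Tag Counting, Demultiplexing and Marker Consolidation for
    Genotyping-by-Sequencing Reads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Extracts per-sample, per-allele read counts and numeric
    genotypes from multiplexed genotyping-by-sequencing (GBS) and RAD-seq
    FASTQ files by exact prefix matching of barcodes and tag sequences
    against recursive indexing trees built in compiled code.  Demultiplexes
    FASTQ files by barcode with restriction-site aware adapter and chimera
    trimming and MD5 manifests for archive deposit.  Imports tag sets from
    common reduced-representation SNP-calling pipelines (paired-tag FASTA,
    alignment SAM, catalog and allele-block formats, and three CSV layouts),
    and consolidates marker sets across projects under stable universal
    names with IUPAC consensus FASTA export and alignment annotation.  A
    seeded synthetic-data generator produces multiplexed FASTQ with known
    per-read ground truth so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    Rcpp,
    Rsamtools,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stringr,
    tibble,
    tidyr,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
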