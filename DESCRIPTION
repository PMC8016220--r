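Package: revmap
Title: Reverse Mapping of Sequence Queries Against FM-Indexed Short Reads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Author: Package Author [aut, cre]
Maintainer: Package Author <author@example.org>
Description: Builds a compressed full-text (FM) index over raw short-read
    sequencing data and runs flexible k-mer queries against it, reversing the
    usual mapping direction: instead of aligning reads to a reference, target
    sequences are searched within the reads. Supports reference-free counting
    of target sequences, genotyping of biallelic SNP sites from VCF-derived
    ref/alt query pairs, detection of pathogen reads spiked into a background
    sample, chunked index construction with merged search results, and a
    seeded simulator for genomes, diploid SNP read sets, and pathogen
    spike-in mixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Biostrings,
    vcfR,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
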