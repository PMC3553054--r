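Package: gbskit
Title: Genotyping-by-Sequencing Toolkit: In Silico Digestion, Read
    Processing, SNP Calling, Annotation and Diversity Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A desk-scale toolkit for reduced-representation
    genotyping-by-sequencing (GBS) experiments. Assesses candidate
    restriction enzymes by in silico digestion of a reference genome,
    demultiplexes barcoded single-end GBS reads with restriction-remnant
    validation and adapter clipping, places reads with a built-in exact
    unique mapper or imported SAM alignments, calls SNPs and short indels
    from pileups with depth, missing-data and minor-allele-frequency
    filters plus heterozygote correction, classifies variants against
    GFF3 gene models (synonymous/nonsynonymous, UTR, splice site, 5 kb
    flanks), and summarises diversity with p-distances, neighbor-joining
    trees and bootstrap consensus. A seeded simulator generates barcoded
    GBS reads with known truth genotypes so every pipeline stage is
    testable end to end, including selective-base complexity-reduction
    protocols.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicAlignments,
    Rsamtools,
    rtracklayer,
    S4Vectors,
    vcfR,
    ape,
    dplyr,
    tidyr,
    tibble,
    purrr,
    stringr,
    readr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
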