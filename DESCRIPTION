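Package: rnaseScout
Title: Characterization and Genomic Scanning of Plant T2/S-Type Ribonucleases
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for characterizing members of the plant T2/S-RNase gene
    family and for locating putative (possibly relict) S-loci in genome
    assemblies. Computes Bjellqvist isoelectric points on mature peptides,
    scans proteins for the five conserved T2-RNase regions and the two
    catalytic-histidine active sites, maps intron insertion points onto
    codon-aware alignments and clusters them into positionally homologous
    sites under a seven-nucleotide window rule, classifies sequences into the
    three land-plant T2/S-RNase classes, and scans genome contigs for class
    III RNase loci flanked by intact or stop-disrupted F-box open reading
    frames. A deterministic synthetic-fixture generator produces proteins,
    gene structures, alignments and planted 2-Mb haplotypes with known truth
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    Biostrings,
    GenomeInfoDb,
    IRanges,
    rtracklayer,
    S4Vectors,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
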