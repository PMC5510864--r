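Package: retroseek
Title: Discovery of Gene Retroduplications from Exome and Whole-Genome
    Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: An integrated pipeline for discovering novel gene
    retroduplications (retrocopies / processed-pseudogene insertions)
    absent from a reference genome. Exon-exon junction evidence is
    collected from exome reads that fail to map to the genome but map
    across spliced exon boundaries, with the false discovery rate
    controlled by coordinate-shifted decoy junction libraries and a
    Poisson zero-false-call model. Insertion sites are localized from
    discordant whole-genome read pairs by average-linkage clustering.
    Downstream analyses include carrier-frequency matrices, fixation-index
    permutation tests, bootstrap population phylogenies with multiscale
    (approximately unbiased) support, expression-association tests,
    permutation-based genomic-feature enrichment, and a simulation of how
    retrocopies erode SNP genotyping in their parent genes. A synthetic
    data generator emulates every input so the whole pipeline is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    Rsamtools,
    rtracklayer,
    ape,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
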