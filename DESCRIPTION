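Package: TagSeqTools
Title: De Novo Transcriptome Evaluation and NlaIII Tag-Based Digital Gene
    Expression
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An integrated toolkit for de novo transcriptome projects that
    combine short-read assembly with tag-based digital gene expression (DGE)
    profiling. Provides multi-length read trimming and sequence-set statistics
    (N50, length classes, insert-size inference), assembly evaluation against a
    gold-standard reference via union-coverage sensitivity and accuracy,
    sequence characterization (six-frame ORF scanning, codon usage, GC by codon
    position, MISA-style microsatellite detection), an in-silico NlaIII/MmeI
    21-bp tag pipeline (tag catalogs, clean-tag filtering, mismatch-tolerant
    mapping, TPM normalization, library-statistics ledgers), pairwise
    differential and specific expression by conditional exact tests with
    hypergeometric term enrichment, and a synthetic-data generator that
    emulates the statistical structure of such experiments so the whole
    pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    IRanges,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
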