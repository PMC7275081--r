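Package: longfuse
Title: Partner-Independent Fusion Gene Detection from Targeted Long-Read
    Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects fusion genes at nucleotide resolution from split-read
    long-read alignments produced by CRISPR-Cas9 targeted enrichment
    (nanopore) sequencing, without prior knowledge of the partner gene or
    breakpoint position. Extracts junction breakends from supplementary
    alignments, clusters them into structural-variant calls with VCF 4.2
    breakend output, annotates both ends with gene models, retains only
    fusions able to produce a continuous transcript on one strand, and
    reports exon/intron breakpoint context, coding-sequence composition and
    breakpoint-spanning validation primers. Also computes the enrichment
    assay's readouts (on-target, breakpoint and fusion coverage and fold
    enrichment, read directionality, time-course accumulation, supporting
    read cutoff sweep), designs strand-directed crRNA panels with sequential
    tiling, and ships a Cas9-enrichment read simulator with truth alignments
    so the whole stack is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicAlignments,
    GenomicRanges,
    IRanges,
    Rsamtools,
    S4Vectors,
    jsonlite,
    rtracklayer,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests:
    igraph,
    optparse,
    testthat (>= 3.0.0),
    VariantAnnotation
Config/testthat/edition: 3
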