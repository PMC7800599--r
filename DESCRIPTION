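Package: promoterscope
Title: Genomic Annotation, Colocalization and Meta-Profiles for ChIP-Seq Peak Sets
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Characterizes transcription-factor binding sites from ChIP-Seq peak
    calls. Partitions a genome into promoter (TSS), gene-end (TES), gene-body and
    intergenic regions from gene models, annotates peak regions by a fixed category
    priority with a minimum-overlap rule, computes pairwise and three-way peak-set
    colocalization (Euler-Venn membership counts), builds averaged signal
    meta-profiles around binding sites with matched random-promoter and
    random-genome controls, and classifies RNAi knockdown expression responses from
    qPCR Ct tables by delta-delta-Ct with reference-gene normalization. Ships a
    synthetic-data generator that plants ground truth (peak categories,
    colocalization rates, signal bumps and dips, fold changes) so the whole
    pipeline is testable end to end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    graphics,
    tools,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    rtracklayer,
    jsonlite,
    optparse
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
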