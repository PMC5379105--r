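Package: circSplice
Title: Back-Splice Junction Detection and Differential Analysis of Circular RNAs
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Anchor-based detection of circular RNA back-splice junctions from
    stranded paired-end RNA-seq reads, joint negative-binomial GLM differential
    expression of circular and cognate linear junctions, a faux-circRNA
    permutation test for positional bias of circRNAs within protein-coding
    transcripts, and CLIP-peak flanking-intron enrichment analysis. Ships a
    fully deterministic synthetic-data generator (genome, annotation, reads,
    counts, CLIP peaks, ground truth) so the whole pipeline is testable
    end-to-end without external downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    SummarizedExperiment,
    rtracklayer,
    yaml
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Transcriptomics, RNASeq, DifferentialExpression, Sequencing
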