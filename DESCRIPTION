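Package: SpliceFusion
Title: Splicing-Graph-Based Gene Fusion Detection from Long-Read RNA-Seq
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects gene fusion events from noisy long-read RNA sequencing
    data using an exon-level reference splicing graph. The package builds
    comprehensive and protein-coding reference splicing graphs from GFF3
    annotation, screens graph alignments for reads spanning multiple gene
    subgraphs, validates candidate fusion junctions by targeted re-alignment,
    clusters supporting reads by breakpoint proximity and exact graph path,
    derives error-corrected consensus sequences, and classifies events into
    confidence tiers via dual re-alignment against the protein-coding graph
    and the linear genome, with splice-motif checks, breakpoint refinement
    to annotated exon boundaries and read-through artifact screening. A
    synthetic benchmark module simulates fusion transcriptomes and error-prone
    long reads and scores calls at the gene-pair and breakpoint level.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer,
    data.table,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
biocViews: Transcriptomics, RNASeq, GeneFusionDetection, LongRead, Alignment
RoxygenNote: 7.3.3
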