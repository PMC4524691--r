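Package: repeatscape
Title: Repeat Landscape Analysis: Annotation Reconciliation, Repeat-Gene
    Association, Exonization, TFBS and miRNA Footprint Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for genome-wide analysis of complex repetitive elements:
    reconciliation of repeat-family annotations from de novo, homology and
    protein-domain evidence with a characterization cascade for unknown
    families; chromosome coverage and genic/intergenic/exonic/intronic
    partition statistics with correlation and binomial enrichment tests;
    an orthologue-alignment cascade that detects repeat-borne indels and
    substitutions and propagates them to amino-acid level; gain/loss
    accounting of transcription-factor binding sites in upstream windows
    with attribution to repeat-overlapping sequence; detection of eroded
    repeat footprints around orthologous pre-miRNAs; and expression
    accounting (RPKM, repeat-family averages, microarray probe assignment,
    small-RNA read processing and mapping).  A synthetic-genome simulator
    with a ground-truth manifest exercises every stage end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
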