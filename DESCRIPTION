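Package: tboxscan
Title: Downstream Analysis of T-Box Transcription-Factor Occupancy:
    Peak Annotation, Co-Binding, Motif Scanning and Binding Biophysics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Reusable downstream pipeline for multi-factor embryonic
    ChIP-seq/RNA-seq studies of T-box transcription factors. Assigns
    binding peaks to nearest genes by summit-to-TSS distance, classifies
    their genomic position (promoter bands, gene body, exon/intron/UTR),
    builds 400-bp binned gene-level occupancy profiles and windowed
    -log10(p) sums, quantifies co-occupancy between factor or stage
    tracks by summit distance, calls shared target genes under a
    two-tier stringency rule, scans peak-flanking sequence with position
    weight matrices on both strands, tests binding enrichment in
    differentially expressed gene sets (Fisher overlap, exact one-tailed
    Mann-Whitney), and fits equilibrium dissociation constants and
    nuclear-concentration occupancy predictions from binding-response
    curves. A synthetic-data module generates genomes, peak tracks,
    motif-bearing sequences, expression tables and binding curves with
    planted structure so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
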