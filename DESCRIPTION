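Package: tfscreen
Title: Direct Transcription-Factor Target Calling from ChIP-seq and
    RNA-seq, with Validation-Assay and Drug-Synergy Toolkit
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Integrates transcription-factor ChIP-seq peak calls with a
    differential-expression table from TF perturbation to call direct
    transcriptional targets: peaks are annotated by signed distance to
    the transcription start site, differentially expressed genes are
    selected by fold-change and adjusted-P cutoffs, and genes with
    TSS-proximal binding plus direction-concordant expression change are
    reported as transactivated or repressed candidates. Companion tools
    cover the downstream bench validation and pharmacology: IUPAC core
    motif scanning of promoter and probe sequences, ChIP-qPCR tiling
    window design and percent-input enrichment, Chou-Talalay
    median-effect fitting with combination-index synergy classification,
    and the small summary statistics such screens report (Fisher's exact
    test on incidence tables, Pearson correlation, proportions, tumor
    volume). A synthetic-data generator plants ground-truth targets so
    the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    graphics,
    IRanges,
    S4Vectors,
    jsonlite,
    rtracklayer,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
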