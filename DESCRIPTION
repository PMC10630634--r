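Package: nascentr
Title: Nascent-Transcriptome Analysis of Antisense Transcription
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing strand-specific nascent transcription
    (GRO-seq style) data with a focus on natural antisense transcripts:
    de novo transcription-unit calling from strand-separated coverage,
    merging novel units with a reference annotation, strand-aware
    sense-antisense pairing and inverse-regulation (ASRG/NARG)
    classification, a self-contained negative-binomial differential
    expression stage (TMM normalisation, dispersion estimation, GLM
    likelihood-ratio test, BH FDR), promoter-proximal pausing
    quantification, transcription-rate estimation from metabolic-labeling
    time courses, delta-delta-Ct qPCR quantification, hypoxia response
    element motif scanning, and a seeded synthetic-data generator that
    emulates the statistical structure of such experiments with
    machine-readable ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    jsonlite,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    withr
Config/testthat/edition: 3
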