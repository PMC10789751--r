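Package: rtkit
Title: Detection and Characterization of Transcription Readthrough from
    Coverage Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects downstream-of-gene (DoG) readthrough transcripts from
    per-base RNA-seq coverage tracks using a rolling-window caller, classifies
    expressed genes as readthrough (RT), non-readthrough (NRT) or undefined
    (UND), and implements the downstream statistics used to characterize
    readthrough in bulk transcriptomes: RT-ratio quantification,
    expression-matched permutation comparisons, hexamer enrichment scoring,
    terminal-intron retention quantification, genomic and epigenomic context
    enrichment, and miRNA seed-match sponge prediction. Includes a synthetic
    data generator that plants readthrough tails, intron retention, sequence
    composition biases and miRNA binding sites with machine-readable ground
    truth, so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomeInfoDb,
    GenomicRanges,
    Biostrings,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
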