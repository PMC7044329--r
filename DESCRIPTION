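Package: terminus
Title: Quantifying Transcription Termination Read-Through and 3'-End
    Processing Defects
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Windowed read-through ratio statistics on nascent-transcription
    (PRO-seq style) and RNA polymerase II occupancy coverage tracks at
    non-polyadenylated gene classes (replication-dependent histone and snRNA
    genes), dual-library (polyA-selected versus ribo-depleted) aberrant
    polyadenylation calling, qPCR unprocessed-transcript fraction and
    ChIP percent-of-input arithmetic, distributed normalized spectral
    abundance factors (dNSAF) from peptide-level spectral counts, and
    TSS-proximal peak co-occupancy analysis, together with seeded synthetic
    data generators with known ground truth for every input the pipeline
    consumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    S4Vectors,
    IRanges,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
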