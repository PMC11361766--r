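Package: m6adecay
Title: m6A Methylation, RNA Decay Kinetics and Reader-Target Integration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Count-level analysis chain linking N6-methyladenosine (m6A)
    hypomethylation to transcript stabilization: MeRIP-seq IP-vs-input
    enrichment and differential methylation calling, ERCC spike-in
    calibrated first-order RNA half-life estimation from transcription
    shutoff time courses, depth-normalized expression contrasts,
    reader (RIP-seq) target calling, and group-shift / set-overlap
    statistics (Wilcoxon rank-sum, Fisher's exact) that join them.
    Includes a negative-binomial simulator with known ground truth for
    every assay, plus quantification helpers for MeRIP-RT-qPCR
    (spike-normalized fold enrichment), RT-qPCR (2^-ddCt), LC-MS/MS
    m6A/A ratios via standard curves, and a proteomic z-score screen.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
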