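Package: rmqc
Title: Risk-Matrix Analysis for Radiotherapy Machine QC Frequencies
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Determines optimal quality-control (QC) test frequencies for a
    radiotherapy machine by failure mode and effects analysis (FMEA) combined
    with a 10x10 risk matrix. Computes TG-100-style severity (S), occurrence
    (O), and detection (D) ranks per failure mode from QC measurement logs,
    service records, and externally computed dose-perturbation tables;
    classifies each (S, O) pair into low/medium/high risk with explicit band
    rules; recommends a test interval per QC item as the first medium-risk
    interval on a tested grid; and evaluates schedules with the efficiency
    metric E = O/D. Includes a synthetic machine-log and dose-effect
    generator with exhaustive ground-truth bookkeeping so every pipeline
    stage is testable without clinical data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
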