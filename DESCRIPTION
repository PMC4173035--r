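Package: segclock
Title: Delayed Negative-Feedback Model of the Mouse Hes7 Segmentation Clock
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates the mouse somite segmentation clock as a two-variable
    (mRNA, protein) delay differential equation in which the Hes7
    transcriptional repressor inhibits its own transcription after a
    composite time delay (transcription + mRNA processing/export +
    translation). Provides delay-budget arithmetic that converts gene
    architecture (insert length, RNA polymerase elongation velocity) into
    delay contributions, a method-of-steps fixed-step integrator,
    closed-form steady-state and Hopf critical-delay companions, oscillation
    metrics (period, amplitude, damping, sustained/damped/arrested
    classification), named genotype scenarios (intron knock-ins, 3'UTR loss,
    intron deletions), parameter scans, and seeded synthetic-data generators
    for noisy expression traces, phase-offset cell populations and
    reference-normalized relative-quantification measurements.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    deSolve
Config/testthat/edition: 3
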