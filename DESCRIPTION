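Package: dmnmeg
Title: Default-Mode-Network Spectral Power and Envelope Connectivity for
    Absence-Epilepsy MEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A reproducible pipeline for source-level analysis of
    magnetoencephalography (MEG) recordings in childhood absence epilepsy:
    selection of ictal, interictal and control segments from annotated
    recordings, depth-weighted minimum-norm inverse estimation at toy
    scale, Welch relative power spectral density with canonical six-band
    aggregation, leakage-corrected amplitude envelope correlation (AEC-c)
    connectivity over the 12-region default mode network with
    node-strength graph summaries, and nonparametric group statistics
    with false-discovery-rate control. Includes a seeded synthetic-data
    generator that emulates the three recording regimes (control,
    interictal, ictal with 3 Hz spike-wave discharges) so the whole
    pipeline is testable end to end without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2,
    optparse
Config/testthat/edition: 3
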