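Package: iednm
Title: Interictal Epileptiform Discharge Detection and Infrared
    Neuromodulation Analysis for Micro-ECoG Recordings
Version: 0.1.0
Authors@R:
    person("iednm", "maintainers", email = "iednm@example.org",
           role = c("aut", "cre"))
Description: Tools for characterising interictal epileptiform discharges
    (IEDs) in multichannel micro-electrocorticography recordings under
    pulsed or continuous infrared neuromodulation (INM) protocols. Provides
    a synthetic recording generator with ground-truth IED injection and a
    configurable thermal-effect model, the standard notch/band-pass/band-stop
    preprocessing chain, a sliding-window adaptive-threshold IED detector
    with an evaluation harness, five temporal and spectral IED features with
    40-second binning, cortical temperature simulation and thermal-phase
    segmentation, and a baseline-normalised trial-similarity statistic
    (truncated-mean Pearson correlation) with significance categories.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
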