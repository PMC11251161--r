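Package: dbsense
Title: Parsing and Analysis of Deep Brain Stimulation Sensing Sessions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for working with sensing data recorded by deep brain
    stimulation (DBS) neurostimulators with local field potential (LFP)
    sensing, in the style of Percept-PC session exports. Parses session
    JSON files into a typed multi-patient data model covering in-clinic
    recordings (Survey, Setup, Streaming sensing modes) and chronic
    recordings (Timeline band-power trends and patient-marked Events),
    merges multi-file batches per patient, and exports FieldTrip-compatible
    MAT containers. Analysis streams include calibration inspection
    (impedances, survey spectra), chronic analytics (circadian band-power
    profiles, event histograms, event-triggered averages, event FFT-snapshot
    summaries), and streaming analytics (zero-phase band filtering,
    ECG-artifact template subtraction, stimulation-transition and broadband
    artifact screening, Welch spectra, Morlet scalograms, and cross-signal
    analysis against wearable accelerometer traces). A seeded synthetic
    session generator with ground-truth sidecars makes every analysis
    testable without clinical data, and a command-line entry point exposes
    the main workflows.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
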