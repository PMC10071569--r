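Package: driftwatch
Title: Online Bioprocess Monitoring from Drift-Time Ion Mobility Spectra
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for automatic evaluation of membrane-inlet ion mobility
    spectrometry (IMS) time series recorded above photobioreactor cultures.
    Provides drift-time physics and reduced-mobility conversions, reactant-ion-peak
    normalization to relative drift time, background-noise and limit-of-detection
    estimation, peak detection and fixed-center Gaussian peak quantification,
    a standard-scaled four-component principal-component state model with
    per-peak score contributions, and a rule engine that maps score trajectories
    to process-control recommendations (continue, harvest or feed, check
    contamination, shade). A synthetic-data module simulates microalgae
    cultivations (logistic growth, day/night illumination, characteristic
    volatile-organic-compound emission peaks) and renders seeded IMS spectra so
    the whole pipeline is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    data.table,
    jsonlite,
    yaml,
    pracma,
    signal
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    optparse
Config/testthat/edition: 3
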