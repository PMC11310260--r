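Package: musuppr
Title: Mu-Suppression EEG Analysis with Source Localization and Neurofeedback Protocols
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for event-related desynchronization analyses of
    the sensorimotor mu rhythm (8-13 Hz). Provides a forward-model synthetic EEG
    generator (spherical head geometry, band-limited oscillatory sources, 1/f
    background), condition-block preprocessing (DC removal, average reference,
    edge trimming), Welch power spectral density estimation, the log-ratio Mu
    Suppression Index (MSI) with one-sample t-tests and repeated-measures ANOVA
    (Greenhouse-Geisser corrected), a weighted minimum-norm inverse solution for
    source-space MSI maps, cluster-based sign-flip permutation contrasts, and a
    four-band threshold neurofeedback protocol simulator with success-rate
    calibration. EDF and an internal float container are supported for data
    exchange.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    igraph,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
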