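Package: somnotools
Title: Sleep Electrophysiology Analysis for Rodent Polysomnography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for rodent sleep electrophysiology: hypnogram
    architecture and fragmentation metrics, Welch spectral analysis with
    delta-band (slow-wave activity) power and time courses, sleep spindle
    detection from continuous-wavelet-transform energy, slow-wave/spindle
    cross-correlation and phase-amplitude coupling (modulation index with
    surrogate calibration), and state-resolved single-unit firing and burst
    metrics. Includes a synthetic polysomnography generator with known ground
    truth (semi-Markov vigilance-state sequences, 1/f background, injected
    slow oscillations and phase-locked spindles, bursty spike trains) and
    readers/writers for EDF signals, CSV hypnograms and event tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
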