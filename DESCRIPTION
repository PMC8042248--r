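Package: scalpHFO
Title: Automated Ripple-Band High-Frequency Oscillation Analysis for Scalp EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detection and characterization of ripple-band (80-250 Hz)
    high-frequency oscillations (HFO) in whole-night scalp EEG recorded with
    the international 10-20 system. Provides a three-stage automated detector
    (Stockwell-entropy baseline thresholding, time-frequency peak isolation,
    and scalp-specific rejection of high-amplitude, low-SNR and bilateral
    events), a bipolar neighbour montage with 52 derivations, N3 sleep
    interval selection, per-event and per-patient HFO features (rate,
    frequency, duration, amplitude, SNR, ripple-band activity), test-retest
    reliability of HFO spatial profiles, cohort statistics linking HFO
    features to age, and a synthetic multichannel EEG simulator with known
    injected events for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
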