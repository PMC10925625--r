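Package: vrsync
Title: Blink-Based Synchronization of EEG and VR Eye-Tracking Streams with an SSVEP Speller Classifier
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the constant hardware offset and jitter between an
    EEG/EMG stream and a VR-headset eye-tracking stream from metronome-paced
    eye blinks: eye-closure onsets (openness below 0.1) are aligned against
    the 90%-of-peak rising crossing of the zero-phase band-pass filtered
    (0.75-5 Hz) EMG blink burst, per-blink offsets are aggregated with a
    3-sigma outlier pass, and trimming strategies are selected by minimal
    standard deviation. Ships the demonstrated downstream consumer, a
    steady-state visually evoked potential (SSVEP) speller classifier based
    on canonical correlation against sinusoidal references with harmonics,
    scored by accuracy and Wolpaw information transfer rate. A synthetic
    multimodal-session simulator (paced blinks on a 120 Hz device grid with
    configurable true offset and jitter; SSVEP responses in 1/f plus 50 Hz
    line noise) makes every estimator testable without hardware. Includes
    timestamp dejittering, anti-aliased downsampling, CSV recording I/O,
    chunked replay, and a command-line interface.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    jsonlite,
    yaml,
    withr,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
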