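Package: vibrotemp
Title: Temperature Inference from Vibroacoustic Needle-Insertion Signals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating tissue-phantom temperature from the
    vibroacoustic signal recorded by a microphone mounted on the proximal end
    of a needle. Provides a synthetic generator of annotated needle-insertion
    recordings (initiation pulse, approach, forward motion through a bubbled
    foam, dwell, retraction, with a controllable temperature-dependent
    spectral effect), envelope-based acoustic event detection with a
    mean-plus-one-sigma amplitude threshold, peaks-per-centimetre event
    density estimation, 100 ms chunk extraction (sliding and peak-centred
    with uniform jitter), mel-spectrogram features, a small convolutional
    regression network trained under recording-grouped fivefold
    cross-validation with waveform augmentation, and evaluation utilities
    (RMSE, per-temperature-group summary tables, violin-plot data and
    per-recording prediction traces). Includes plain-R WAV readers/writers
    and dataset manifest handling so the full pipeline runs offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
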