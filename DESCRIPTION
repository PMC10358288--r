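Package: sleepperiods
Title: Sleep-Period Detection and Time-Matched EEG Spectrograms from
    Polysomnography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Segments overnight sleep-stage annotation sequences (hypnograms)
    into NREM and REM sleep periods with an explicit, reproducible rule set
    (minimum/maximum period durations, wake-break handling, arousal and
    lightening-of-sleep cut points for over-long NREM periods), and computes a
    multitaper EEG spectrogram on a fixed 901-point frequency grid,
    time-aligned to the scoring epochs. Reads EDF/EDF+ polysomnography files
    with embedded stage annotations as well as plain-text two-column
    annotation files, applies optional frequency and epoch-quality filters,
    renders a hypnogram-plus-spectrogram figure, and writes period and stage
    listings and an exportable power matrix. Includes a synthetic-data
    generator (template hypnograms with known ground truth, band-structured
    EEG, EDF+ writer) so the whole pipeline is testable without clinical
    recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    graphics,
    grDevices,
    utils,
    jsonlite,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
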