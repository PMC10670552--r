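Package: ecgsqa
Title: Automated Single-Lead ECG Signal Quality Assessment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Classifies 10-second single-lead electrocardiogram (ECG)
    segments as acceptable or unacceptable for diagnostic use. Segments are
    amplitude-normalized, converted to Hann-windowed short-time Fourier
    transform magnitude spectrograms, and scored by a compact CNN-LSTM
    classifier trained with the Adam optimizer. Includes waveform readers
    for delimited-text and WAV files, band-limited resampling, labeled-region
    segmentation, class-ratio-controlled corpus construction with optional
    group-aware (leakage-safe) splitting, sensitivity/specificity/accuracy/F1
    evaluation reports, a synthetic ECG-and-noise generator covering the four
    canonical contamination families (baseline wander, powerline, muscle
    noise, electrode motion) at controlled signal-to-noise ratios, and a
    command-line workflow for the full simulate-train-evaluate loop.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
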