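Package: synergait
Title: Muscle Synergy Analysis of Treadmill and Robotic-Guided Gait
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for the modular (muscle synergy) analysis of multi-channel
    surface EMG recorded during treadmill and robotic-guided walking. Implements
    the full processing chain: band-pass filtering, rectification and RMS
    smoothing of raw EMG, gait-cycle segmentation and time normalization to a
    101-point cycle, amplitude normalization across walking conditions,
    non-negative matrix factorization into motor modules and activation
    signals, variance-accounted-for (VAF) quality assessment overall, per
    muscle and per gait subphase, module-count selection, fixed-module
    activation re-fitting, activation-timing statistics (subphase integrals,
    on/off detection), and joint range-of-motion / range-of-force summaries.
    Includes a seeded synthetic gait EMG generator with known modular ground
    truth so that every stage can be validated end to end without recorded
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    pracma,
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
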