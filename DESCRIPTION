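Package: eegdays
Title: Cross-Day Calibration Protocols and Consensus Feature Selection
    for EEG Emotion Classification
Version: 0.1.0
Authors@R:
    person("EEG Days", "Maintainers", email = "maintainers@eegdays.example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying and mitigating day-to-day variability in
    EEG-based emotion classification. Provides Welch band-power feature
    extraction from multichannel 5-s epochs (mastoid re-referencing,
    anti-alias decimation, six canonical frequency bands), three classifier
    calibration protocols over multi-day recordings (within-day, standard
    cross-day, and learning-N-days-information with combinatorial day
    splits and a factor-12 sample budget), a modified recursive feature
    elimination that ranks features by accuracy loss with cross-fold
    consensus voting, and a synthetic multi-day EEG generator (signal
    level and feature level) with controllable class effects and day drift
    so the full pipeline is testable without access to recordings.
    Includes confusion matrices, paired comparisons, tidy delimited-text
    result output and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
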