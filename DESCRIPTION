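Package: mobispec
Title: Mobile EEG Spectral Analysis of Guided Art Viewing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for analysing four-channel mobile EEG recorded
    while freely moving subjects view an art exhibit. Implements
    accelerometer-gated multimodal artifact rejection, log-driven epoching,
    Thomson multitaper power spectral density estimation with baseline
    correction, Ward hierarchical clustering with Calinski-Harabasz model
    selection and epoch-to-variable correspondence analysis, band-wise
    (beta/alpha) condition contrasts against baseline and randomly selected
    non-favorite-painting controls, and demographic/aesthetic-preference
    statistics. Ships a synthetic-data generator that emulates the statistical
    structure of such museum recordings (1/f background, band-limited rhythms,
    planted frontal beta suppression, blink/motion artifacts co-occurring with
    accelerometer excursions, event logs and questionnaires) so every stage is
    testable without access to raw recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    yaml
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
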