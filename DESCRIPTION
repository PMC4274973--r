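Package: asindex
Title: Activation Synchrony Index for Neonatal EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies interhemispheric synchrony in discontinuous neonatal
    EEG with the activation synchrony index (ASI): band-pass preprocessing and
    pre-emphasis, amplitude-envelope extraction, equal-occupancy quantization,
    and a lagged mutual-information ratio contrasting zero-lag dependency of
    homotopic bipolar derivations against long-lag chance coincidence.
    Includes windowed epoch schemes with a mean-squared-difference test-retest
    stability criterion, a thresholded min-of-means classifier of EEG
    normality with ROC/AUC evaluation, a synthetic trace-alternant EEG
    generator with a tunable interhemispheric burst-timing plant, and EDF/EDF+
    input/output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    signal,
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
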