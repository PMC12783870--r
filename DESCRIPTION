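Package: avtbw
Title: Audio-Visual Temporal Binding Windows from Simultaneity Judgements
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designing, simulating, and analysing audio-visual
    simultaneity-judgement (SJ) experiments with rhythmic and speech-like
    amplitude-modulated streams. Generates sinusoidal and quasi-rhythmic
    modulation envelopes, validates their spectral content by FFT, builds
    randomized SOA-by-condition trial lists, simulates rating-scale
    observers from a ground-truth Gaussian simultaneity model, recodes
    5-point ratings into synchronous/asynchronous proportions, and fits
    bounded Gaussian and side-split logistic psychometric functions to
    estimate temporal binding windows (TBW), points of subjective
    simultaneity (PSS), and leading-sense slopes and thresholds, with
    adjusted R-squared subject-exclusion rules.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
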