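Package: meabands
Title: Oscillation-Band Detection and Occurrence Modelling for Multichannel
    MEA Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for carbachol-induced network oscillations in
    multichannel microelectrode-array (MEA) recordings of organotypic
    hippocampal slice cultures. Provides downsampling and Butterworth
    high-pass preprocessing, sliding-window DPSS multitaper spectral
    estimation with 1/f correction and line-harmonic excision,
    prominence-thresholded detection of delta/theta/beta/gamma oscillation
    bands with mode-based categorization, binomial logistic modelling of
    per-culture oscillation occurrence with AIC model selection, and a
    deterministic synthetic-recording generator so the whole pipeline can be
    exercised against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    car,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
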