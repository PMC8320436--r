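Package: semgmap
Title: Mapping Upper-Limb Surface EMG to Clinical Motor Scores in Chronic Stroke
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for data-driven clinical assessment of the paretic upper limb
    from multi-channel surface electromyography (sEMG). Implements zero-phase
    Butterworth/notch preprocessing with pause excision and overlapping-epoch
    segmentation, the classic time-domain feature set (MAV, ZC, SSC, RMS, WL),
    linear-envelope activation levels and co-contraction indices, a three-layer
    backpropagation network trained by Levenberg-Marquardt with Bayesian
    regularization that maps epoch features to Fugl-Meyer (FMA-SE, FMA-WH) and
    Modified Ashworth (MAS) scores, the full cross-validation and sweep
    evaluation protocols, and a synthetic stroke cohort generator for
    end-to-end testing without clinical data.
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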