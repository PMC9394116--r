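Package: phenofuse
Title: Multimodal Spectral Fusion for Plant Stress Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: End-to-end multimodal fusion of visible/near-infrared reflectance
    spectra and chlorophyll-fluorescence kinetic curves for classifying plant
    abiotic stress. Implements a gated-attention 1-D convolutional base
    classifier for single spectral sources, three fusion levels (raw-vector
    concatenation, learned-feature fusion, and decision fusion trained with a
    joint multi-head cross-entropy loss), two-stage fusion baselines, an
    RBF-SVM reference classifier, the reflectance-calibration and
    wavelet-denoising preprocessing chain, stratified dataset splitting, and a
    synthetic multimodal data generator with controllable cross-modal
    complementarity for benchmarking fusion against single-source models.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    e1071,
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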