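Package: qusdl
Title: Quantitative Ultrasound Parametric Imaging and Deep Learning for
    Chemotherapy Response Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantitative ultrasound (QUS) spectroscopy and
    image-based treatment-response prediction. Simulates radiofrequency
    (RF) ultrasound frames and multi-plane patient cohorts with known
    acoustic ground truth; estimates spectral parameters (mid-band fit,
    spectral slope, 0-MHz intercept, effective scatterer diameter and
    effective acoustic concentration) via reference-phantom power-spectrum
    normalization and spherical Gaussian form-factor inversion; builds
    sliding-window multi-parametric maps over a tumor core and its margin;
    trains a two-stage convolutional (residual or residual-attention)
    and fully connected model for patient-level response prediction; and
    evaluates predictions with classification metrics, Kaplan-Meier and
    log-rank survival comparison, and occlusion-based prediction
    difference maps.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    signal,
    mgcv,
    survival,
    pROC,
    EBImage,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
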