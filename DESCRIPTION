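Package: iopscreen
Title: Non-Contact Screening for Elevated Intraocular Pressure from
    Scheimpflug Imaging and Clinical Parameters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Desk-scale, fully synthetic re-implementation of a multimodal
    pipeline for non-contact detection of ocular hypertension (intraocular
    pressure > 21 mmHg). Provides a calibrated Scheimpflug-like phantom
    generator with artifact injection, cycle-consistent image augmentation
    with a classic-jitter fallback, a Broad Learning System quality gate
    with Canny-style geometric integrity screening, a windowed-attention
    image encoder with transfer-learning freeze policies, a
    Kolmogorov-Arnold spline network fusing pooled image features with
    standardized clinical attributes, stratified patient-grouped data
    splitting, confusion-matrix metrics including the Matthews correlation
    coefficient, classical machine-learning baselines, Grad-CAM region
    attribution against phantom ground-truth masks, and analytic tonometry
    correction formulas. All gradient-based components run on a small
    reverse-mode automatic-differentiation core included in the package.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    png,
    jsonlite,
    yaml,
    EBImage,
    e1071,
    randomForest
Suggests:
    testthat (>= 3.0.0),
    splines,
    MASS,
    optparse
Config/testthat/edition: 3
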