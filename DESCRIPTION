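Package: rgbLNC
Title: Multi-Scale Estimation of Rice Leaf Nitrogen Concentration from
    RGB Color Indices
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for estimating rice leaf nitrogen concentration (LNC, %)
    from consumer-grade RGB imagery at leaf, canopy, and plot scales.
    Provides vegetation segmentation (Otsu binarization for white-background
    leaf scans; green-minus-red thresholding for field scenes), thirteen RGB
    color indices computed from foreground channel means, stepwise multiple
    linear regression with forward-5%/backward-10% significance criteria,
    leave-one-out and cross-site validation, and R2/RMSE/NRMSE evaluation
    with quality banding. A synthetic-scene generator emulates leaf scans,
    canopy photographs, and plot mosaics with known ground truth so the
    whole pipeline is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    png,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
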