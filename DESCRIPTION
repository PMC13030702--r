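Package: milkcv
Title: Machine-Vision Creamatocrit for Human Milk Microcapillaries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automated creamatocrit analysis of centrifuged human-milk
    microcapillary images. Segments a capillary into seal, serum and cream
    phases by thresholding, contour geometry and axial intensity gradients;
    converts the cream fraction to fat percentage and energy density with
    closed-form analog-versus-digital uncertainty budgets; extracts
    per-channel intensity-histogram feature vectors; estimates the cream
    fraction by Gaussian-process regression (rational quadratic and related
    kernels) and support-vector baselines; and ships a synthetic capillary
    renderer plus illumination quality-control statistics so the whole
    pipeline is testable without clinical images.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    e1071,
    grDevices,
    jsonlite,
    png,
    stats,
    tiff,
    tools,
    utils
Suggests:
    jpeg,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
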