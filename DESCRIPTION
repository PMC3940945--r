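Package: ihcquant
Title: Whole-Slide and Hot-Spot Quantification of Immunohistochemical Stains
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies immunohistochemically stained tissue sections from
    calibrated RGB rasters: color deconvolution of chromogen and counterstain
    by Beer-Lambert optical-density unmixing, per-slide Otsu threshold
    optimization, immunoreactive-area fraction, micro-vessel density with
    gap-bridging morphological closing, digital 25-dot Chalkley counting,
    density-based hot-spot selection at fixed physical area, discrete
    immunoreactive-cell detection and density in cells per 0.1 mm2, and the
    cohort-level statistical comparison of whole-slide versus hot-spot
    analysis (exclusion filtering, Pearson correlations, interobserver
    variability). Includes a synthetic slide generator with homogeneous
    Poisson and clustered parent-offspring spatial processes and full ground
    truth, so every stage is testable without patient material.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    png,
    tiff,
    stats,
    grDevices,
    graphics,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
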