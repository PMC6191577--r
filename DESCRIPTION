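Package: canospec
Title: Canopy Spectral Indices, Green-Pixel Analysis and PLSR for Early
    Wheat Biomass and Nitrogen Status
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for assessing biomass and nitrogen status of cereal
    canopies at early growth stages from proximal sensing data.
    Implements green-pixel segmentation of RGB canopy photographs by
    hue-saturation-brightness thresholds, the normalized-difference
    spectral index (NDSI) battery used for wheat nitrogen diagnostics,
    exhaustive two-band NDSI optimization against plot traits ("contour
    maps" of coefficients of determination), simple linear and quadratic
    regression evaluation with significance stars, and partial least
    squares regression of traits on 400-1000 nm reflectance with k-fold
    cross-validation.  A synthetic canopy-scene generator (traits with a
    nitrogen-dilution structure, soil-vegetation linear spectral mixing,
    and RGB images with known green fraction) provides fully reproducible
    test data for the whole chain.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    png,
    jsonlite,
    mixOmics
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    lattice
Config/testthat/edition: 3
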