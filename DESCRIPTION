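Package: droughtfeat
Title: Image-Derived Drought-Response Features for Cereal Phenotyping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies plant drought response from RGB images of single
    pot-grown plants and of field plots. Segments plants from the background
    in HSI colour space, gates greenness pixels with the excess-green and
    excess-red chromaticity indices, and derives four drought-related
    features from the binary plant mask: the greenness plant area ratio
    (GPAR, a stay-green proxy) and three leaf-rolling shape descriptors
    (TBR, PAR, TCR) built on projected area, edge-pixel perimeter, bounding
    rectangle and rasterised convex hull. Includes time-series analytics
    (first derivatives, leaf-rolling onset detection), one-way ANOVA and
    Pearson correlation helpers for group discrimination, and a seeded
    synthetic plant/plot image generator with exact ground-truth masks for
    validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    EBImage,
    grDevices,
    jsonlite,
    png,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
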