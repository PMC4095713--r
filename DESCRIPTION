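Package: pulpmorph
Title: Morphometry of Dental Pulp Fibroblasts Across Tooth Development Stages
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Quantitative morphometry of dental pulp fibroblast populations in
    developing tooth germs. Provides colour-threshold segmentation of stained
    micrographs, per-cell measurement of area, perimeter and form factor,
    case- and group-level descriptive statistics with fixed-width histograms
    and Gaussian overlays, one-way ANOVA and two-sample t tests, mean-value
    scaled relative distances for intragroup similarity and intergroup stage
    separation, perimeter-versus-area regression with a regression-line
    proximity ratio, and a seeded synthetic-study generator that renders
    segmentable images of star-like and fusiform cells with exact polygonal
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    grDevices,
    utils,
    png,
    EBImage,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
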