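Package: leafangler
Title: Leaf Angle Measurement from Time-Lapse Plant Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Measures per-leaf angles (degrees from vertical) of maize- and
    sorghum-like plants from time-ordered side-view images. A frame is
    segmented into plant and background (blue-channel extraction, unsharp
    sharpening, complement, Otsu-initialised thresholding), the binary mask
    is cleaned (thickening, gap bridging, closing, speckle removal) and
    optionally skeletonized and pruned, and within each user-declared leaf
    region of interest the angle of the leaf blade is read off the
    orientation of the moment-matched ellipse of the largest connected
    component. Angle trajectories across a series are exported as CSV with
    occluded frames recorded as NaN. A synthetic plant-image generator with
    known ground-truth geometry (wilting drift, jitter, noise, occlusion)
    makes every stage testable without real data, and a validation helper
    reports Pearson correlation and mean absolute error against ground
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    igraph,
    png,
    purrr,
    rlang,
    tibble,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
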