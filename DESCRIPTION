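Package: veinmap
Title: Multisensory Detection and 3D Localization of Peripheral Subcutaneous Veins
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detection of peripheral subcutaneous veins in short-wave infrared
    (SWIR) reflectance images and their localization in 3D using registered
    time-of-flight (TOF) range data. Implements the full processing chain:
    Otsu foreground segmentation with dual dilated edge-discarding masks,
    contrast-limited adaptive histogram equalization and percentile intensity
    adjustment, vein extraction by a maximum-curvature ridge method and by
    3-cluster k-means intensity clustering, radial lens-distortion correction,
    RANSAC estimation of the 2D linear map between the TOF and SWIR pixel
    grids, fusion of depth into the SWIR frame (SWIR-D), export of labelled
    3D vein point clouds, pixel-level detection metrics, and a seeded
    synthetic phantom generator for end-to-end validation without cameras.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    EBImage,
    jsonlite,
    png,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
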