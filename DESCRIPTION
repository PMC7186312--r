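Package: fibretrace
Title: Curvelet and Fiber-Tracing Quantification of Fibrillar Collagen Images
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying fibrillar collagen organization in
    two-dimensional grayscale microscopy images such as second harmonic
    generation (SHG) micrographs. Implements a tight-frame fast discrete
    curvelet transform with frequency-wedge extraction and an exact inverse,
    a curvelet-based local orientation analysis mode, a distance-transform
    fiber tracer that nucleates, extends and links individual fibers,
    axial circular statistics (orientation, alignment, dispersion), tumor
    boundary relative-angle analysis with heatmaps, region-of-interest
    tools with intensity statistics, a seeded synthetic fiber image
    generator with per-fiber ground truth, and a deterministic batch
    runner with CSV and TIFF outputs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    jsonlite,
    mgcv,
    parallel,
    stats,
    tiff,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
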