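Package: omagr
Title: Wide-Field Optical Microangiography (OMAG) Processing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
                  role = c("aut", "cre"))
Description: Processing pipeline for optical coherence tomography based
    microangiography (OMAG) of the retina: complex-signal differentiation of
    repeated B-scans into flow contrast, bulk-motion compensation by
    cross-correlation registration, dynamic-programming retinal layer
    segmentation with anatomical slab extraction, Gaussian-filtered maximum
    amplitude en face projection with depth-coded color compositing, and
    stitching of overlapping scan cubes into wide-field composites. Includes
    a synthetic complex-speckle retina phantom with known layer, vessel and
    motion ground truth so every stage is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    png,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
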