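Package: coralmesh
Title: Mesh-Based Morphometrics for Photogrammetric Coral Colony Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Measurement and analysis toolkit for triangulated 3D models of
    coral colonies produced by structure-from-motion photogrammetry. Reads
    and writes Wavefront OBJ meshes, validates and repairs them (boundary
    loop detection, flat hole filling), and computes surface area, enclosed
    volume and label-restricted (effective) surface area. Calibrates model
    units to centimetres from imaged reference objects, rigidly aligns
    sampled to unsampled colony models by iterative closest point, and
    derives the full suite of colony morphometrics used in coral digitisation
    studies: theoretic surface area and volume, biosurface, biomass, sample
    scale percentages and the associated error statistics. Includes a
    sharpness-based video frame selector for preparing reconstruction input
    and parametric synthetic colony generators (massive, branched, tabular,
    foliose growth forms) with analytic ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    png,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    tiff,
    withr
Config/testthat/edition: 3
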