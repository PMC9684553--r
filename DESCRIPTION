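Package: xrftopo
Title: Self-Absorption Correction and 3D Topography Reconstruction for Soft
    X-Ray Fluorescence Microscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward simulation of low-energy multi-detector X-ray fluorescence
    (XRF) imaging with voxel-level self-absorption, fundamental-parameter
    quantification, iterative thickness-map retrieval from scanning
    transmission (STXM) data, and a ray-tracing inverse reconstruction that
    recovers a 3D sample topography from 2D XRF count maps acquired on
    multi-detector systems. The recovered topography is used to correct
    elemental count maps for self-absorption, with quantitative evaluation
    metrics and a command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    tiff,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
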