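Package: casm
Title: Cartilage Surface Mapping and Surface-Based Statistical Parametric Mapping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for whole-joint cartilage thickness analysis on triangle
    meshes of knee bone surfaces. Measures per-vertex cartilage thickness
    either from paired inner/outer surfaces by normal ray casting or from
    one-dimensional image intensity profiles via model-based deconvolution,
    registers subject surfaces to canonical templates with a closed-form
    similarity transform followed by thin-plate spline refinement, and fits
    vertex-wise general linear models of thickness against demographic,
    radiographic and MRI pathology covariates with multiple-comparison
    control by the minimum of random field theory and false discovery rate
    thresholds. A synthetic data generator produces canonical patches,
    subject geometry, covariate tables and thickness fields with known
    ground truth so the full pipeline is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Matrix,
    tibble,
    dplyr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
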