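Package: dotcal
Title: Data Self-Calibration for High-Density Parallel-Plate Diffuse
    Optical Tomography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for continuous-wave diffuse optical tomography (DOT) of
    the breast in a high-density parallel-plate transmission geometry.
    Implements construction of a virtual homogeneous reference directly
    from task measurements via per-source-detector-distance maxima
    (data self-calibration), alongside conventional reference-phantom
    calibration, a finite-element diffusion forward solver with Robin
    boundary conditions, Tikhonov-regularized Gauss-Newton absorption
    reconstruction, hemoglobin spectral unmixing, and a synthetic-data
    generator (diffusion-based and voxel Monte Carlo) for slab phantoms
    with cylindrical inclusions.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    methods,
    stats,
    utils,
    jsonlite,
    yaml,
    RNifti,
    Rcpp
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
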