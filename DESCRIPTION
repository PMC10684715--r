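Package: unwrap3d
Title: Three-Dimensional MRI Phase Unwrapping by Region Partitioning and
    Local Polynomial Modeling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Robust three-dimensional phase unwrapping for gradient-echo MRI,
    intended as a preprocessing step for quantitative susceptibility mapping
    and other phase-sensitive applications. The wrapped phase volume is split
    into six principal-value subintervals, noisy connector voxels are excised
    so that no initial region hides a 2*pi wrap, and the surviving connected
    components are classified into wrap-free blocks and residual voxels.
    Blocks are then merged nearest-first by estimating a single integer 2*pi
    offset per block from a local three-dimensional polynomial model fitted by
    least squares across the block interface, and the remaining residual
    voxels are unwrapped one at a time by quality-guided region growing with
    windowed polynomial fits. Includes synthetic phantom generators
    (Gaussian-bump and variable-gradient volumes with complex Gaussian noise),
    a misclassification-ratio benchmark harness, NIfTI input/output, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml,
    MASS
Config/testthat/edition: 3
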