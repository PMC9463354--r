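Package: bzdecon
Title: Bezier Curve Deconvolution for DSC-MRI Perfusion Quantification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantification of cerebral perfusion (CBF, CBV, MTT, bolus delay
    and dispersion) from dynamic susceptibility contrast MRI concentration
    curves by deconvolution with cubic Bezier residue functions, fitted by
    maximum a posteriori estimation in a Bayesian framework. Includes a
    block-circulant singular value decomposition (oSVD) reference method with
    oscillation-index regularization, a complete simulation framework
    (gamma-variate arterial input function, gamma-family residue functions,
    Rician signal noise, bolus delay and dispersion), evaluation drivers for
    CBF-ratio and residue-RMSE benchmarking, and voxelwise map fitting with
    NIfTI input and output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    RNifti
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    MASS
Config/testthat/edition: 3
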