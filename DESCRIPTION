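Package: dotrecon
Title: Frequency-Domain Diffuse Optical Tomography: Simulation, Iterative and
    Learned Image Reconstruction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for two-dimensional frequency-domain diffuse optical
    tomography (FD-DOT) on circular phantoms. Provides a P1 finite-element
    forward solver for the frequency-domain diffusion equation with Robin
    boundary conditions, a random phantom and dataset generator producing
    noisy boundary measurements together with 64x64 ground-truth rasters of
    the absorption and reduced scattering coefficients, a Tikhonov-regularized
    Newton reconstruction baseline, a compact convolutional network that maps
    boundary data directly to property images, and MSE/PSNR/SSIM evaluation
    utilities for comparing reconstruction methods.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
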