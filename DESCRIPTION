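Package: scintiden
Title: Denoising of Low-Dose Planar Bone Scintigraphy with a Convolutional Autoencoder
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for studying acquisition-time dose reduction in planar bone
    scintigraphy. Provides a procedural anatomical phantom with Poisson count
    acquisition and binomial thinning to emulate shortened-acquisition (low-dose)
    protocols; an enhanced convolutional autoencoder (multi-scale feature blocks,
    channel attention, strided downsampling, efficient residual decoder blocks)
    trained with a hybrid mean-squared-error plus structural-similarity loss; and
    a quantitative evaluation stack with PSNR/SSIM metrics, per-dose summaries,
    paired t-tests and TOST equivalence testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    png,
    yaml,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
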