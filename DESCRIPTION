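Package: sctforge
Title: Synthetic CT Generation from CBCT with Composite Losses and
    Feature-Based Evaluation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Toolkit for cone-beam CT (CBCT) artifact reduction by
    image-to-image translation. Trains a fully convolutional DenseNet to
    map CBCT axial slices to synthetic planning-CT slices under four loss
    compositions (L1, L1+perceptual, L1+SSIM, L1+perceptual+SSIM), and
    evaluates the outputs with conventional similarity metrics (MAE, SSIM,
    PSNR), a feature-mapping ratio built on nonlinear scale-space keypoints
    with binary descriptors and Hamming matching, and dosimetric comparison
    (gamma index, absolute dose difference). A seeded digital head-phantom
    simulator provides paired CT/CBCT slices and dose grids so the whole
    pipeline runs at desk scale.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    Rcpp,
    RNifti,
    EBImage,
    jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
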