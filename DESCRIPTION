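Package: pectovol
Title: Two-Stage Pectoralis Muscle Volumetry from Chest CT
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Volumetric segmentation and quantification of the pectoralis
    major muscle from chest computed tomography. A lightweight convolutional
    range-detection network locates the vertical (axial) extent of the muscle
    on fused multichannel coronal images sampled from an isotropically
    resampled volume; an attention-gated U-Net then segments each axial slice
    within that range. Morphological and connected-component post-processing,
    inter-slice interpolation, muscle volume and density quantification,
    follow-up scan comparison with outlier screening, and a synthetic labeled
    chest-CT phantom generator for training and validation are included. The
    networks, their losses and the training loops are implemented natively in
    R with C++ convolution kernels.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    EBImage,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
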