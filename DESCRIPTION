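Package: thinCT
Title: Through-Plane Super-Resolution Synthesis of Thin-Slice CT
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Synthesizes thin-slice (1 mm) chest CT from thick-slice (5 mm)
    CT with a convolutional-transformer hybrid encoder-decoder that recovers
    masked through-plane positions from visible slices, trained with an
    AdamW protocol keyed to validation PSNR.  Includes a paired lung-phantom
    simulator with a slice-sensitivity-profile degradation model, sliding
    window whole-volume inference with overlap averaging, a bicubic
    interpolation baseline, PSNR/SSIM image-quality evaluation, and the
    diagnostic-accuracy statistics used in reader studies (McNemar, DeLong,
    permutation tests, Likert non-inferiority, bootstrap confidence
    intervals).  Volumes are read and written as NIfTI-1 or MetaImage with
    slice-spacing metadata.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    RNifti,
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
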