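Package: lungwater
Title: Automated Lung Water Density Mapping from Proton-Density-Weighted MRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies lung water density (LWD) from 3D proton-density-weighted
    thoracic MR volumes. Implements the full automated pipeline: lung
    segmentation (a weight-free classical geometric method and a compact
    trainable residual U-Net with Soft-Jaccard loss), automated placement of a
    circular hepatic reference region under the right lung, surface-coil
    shading correction by slice-wise Tikhonov-regularized least-squares fitting
    with L-curve selection of the smoothing parameter, pixel-wise LWD mapping
    anchored to a 70% hepatic water density, and global/regional
    (anterior-mid-posterior, left-right) summaries. Ships digital vial and
    thorax phantom generators with known ground truth, and the vial-phantom
    agreement analysis (regression, Bland-Altman, intraclass correlation).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    RNifti,
    jsonlite,
    Rcpp,
    EBImage
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
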