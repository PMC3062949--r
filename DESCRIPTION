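Package: tubularity
Title: Multiscale Hessian Tubularity Filtering for 3D Images with Automatic Noise-Suppression Selection
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Enhancement of tubular structures (blood vessels, nerve fibres,
    airways) in 3D gray-scale volumes using multiscale Hessian eigenvalue
    analysis. Implements Gaussian scale-space smoothing and gamma-normalized
    Gaussian derivatives, per-voxel symmetric 3x3 eigen-decomposition, the
    Frangi vesselness and Sato line measures, and a per-voxel maximum-over-
    scales response. The background noise-suppression parameter of the Frangi
    measure is selected fully automatically as one tenth of the maximum image
    Laplacian, removing the last manual tuning step from the filter. Ships a
    synthetic phantom generator (curved and straight tubes with Gaussian or
    bar cross-sections, blob and plate distractors, polynomial backgrounds,
    Gaussian noise), MSE/PSNR quality metrics, maximum intensity projection,
    and volume I/O for TIFF stacks, NRRD and MetaImage formats.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    Rcpp,
    tiff,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
biocViews: ImageProcessing, Visualization, Software
RoxygenNote: 7.3.3
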