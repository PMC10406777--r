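Package: ssimaug
Title: Statistical Shape and Intensity Model Based Augmentation of 3D Images
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Builds statistical shape and intensity models (SSIM) from
    co-registered segmented 3D volumes: shape as a PCA point distribution
    model over corresponded tetrahedral-mesh vertices after generalized
    Procrustes alignment, and intensity as a PCA over per-tetrahedron
    Bernstein-polynomial coefficients encoding the image interior. Constrained
    random instances are sampled from both models and synthesized into new
    training images by mirror-based structure cleaning, thin-plate-spline
    warping, painting of the encoded instance intensities, and rigid
    realignment. Includes a parametric phantom generator so the whole
    pipeline is testable without clinical data, plus readers and writers for
    NIfTI, MetaImage, VTK legacy tetrahedral meshes and ASCII PLY surfaces.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
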