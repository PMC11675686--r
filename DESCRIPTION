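Package: fltvae
Title: Unsupervised Latent-Space Scoring of False-Lumen Thrombosis in Aortic Cross-Sections
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for unsupervised classification of false-lumen thrombosis in
    aortic cross-sectional images after Frozen Elephant Trunk surgery. Provides a
    synthetic vessel-phantom generator with ground-truth lumen and thrombus masks,
    curved multiplanar reslicing of 3D volumes perpendicular to a centerline using
    rotation-minimizing frames, a two-dimensional-latent convolutional variational
    autoencoder trained on 64x64 cross-sections, latent-space partitioning into
    thrombus and no-thrombus subspaces, and per-slice and per-dataset thrombus
    scores with pseudo-color score tracks. A reproducible pipeline ties the stages
    together behind a small command-line wrapper.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices,
    graphics,
    tools
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
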