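Package: spikeCT
Title: Non-Destructive Spike Phenotyping from Micro-CT Slice Stacks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for quantifying cereal spike architecture
    from X-ray micro-CT slice images. Transaxial 8-bit slices are cleaned of
    the specimen-holder ring, grain tissue is segmented per slice by a small
    encoder-decoder convolutional network followed by mask-assisted Otsu
    thresholding, and the binarized slices are stacked into a 3D "virtual
    spike". Individual grains are isolated by density-based clustering of the
    voxel point cloud and measured: per-grain volume, alpha-shape surface
    area, oriented-bounding-box length/width/thickness, and bottom-up
    position along the spike, plus spike length, grain number and per-spike
    totals. A synthetic spike phantom generator with analytic ground truth
    (ellipsoidal grains on a rachis, holder ring, noise, impurities) makes
    every stage testable without scanner data, and validation utilities
    provide virtual-vs-manual correlation and group comparison statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    EBImage,
    RNifti,
    png,
    Rcpp,
    stats,
    utils,
    grDevices
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
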