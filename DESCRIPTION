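Package: cytosep
Title: Unsupervised Cell and Background Separation for Cytology Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Separates foreground cells from redundant slide backgrounds in
    liquid-based cytology images without segmentation annotation. A small
    encoder-decoder network (a dual-frame U-Net variant) is trained with a
    batch-level loss combining the nuclear norm of the unfolded background,
    an l2,1 group-sparsity penalty on the per-pixel foreground channel
    vectors, and anisotropic total variation. The package also provides the
    robust principal component analysis (RPCA) baseline solved by the
    alternating direction method of multipliers, threshold-based semantic
    segmentation with Dice evaluation, a synthetic cytology-image generator
    with ground truth, and image/mask input-output plus a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    generics,
    Rcpp,
    ggplot2,
    png,
    stats,
    tibble,
    tiff,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
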