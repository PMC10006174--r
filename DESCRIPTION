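Package: pixplore
Title: Segmentation-Free Pixel-Level Phenotyping for Imaging Mass Cytometry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Pixel-level analysis of multiplexed imaging mass cytometry
    (IMC) data without cell segmentation. Provides arcsinh preprocessing
    with percentile-based maximum-signal thresholding, a hierarchical
    stochastic neighbor embedding (HSNE) style multi-scale landmark
    hierarchy over pixels with drill-down selection, density-based
    clustering of landmark embeddings, signature-driven cell-type calling,
    back-projection of pixel classes onto the tissue raster as colored
    overlays, and region-of-interest quantification of double-positive
    pixels with an exact one-tailed Mann-Whitney test. Includes a synthetic
    multiplexed-image generator with planted regions and ground-truth
    label maps for fully reproducible end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    grDevices,
    Rcpp,
    RANN,
    tiff,
    png,
    yaml,
    digest
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite
Config/testthat/edition: 3
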