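Package: dropcount
Title: Counting Undigested Grains in Dairy-Cattle Dropping Images by Density-Map Regression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for counting small crowded objects -- undigested cereal
    grains in images of dairy-cattle droppings -- by density-map regression.
    Dot annotations marking grain centers are converted into Gaussian density
    surfaces; two fully convolutional encoder-decoder networks (an FCRN
    variant and a U-Net variant) are trained to regress those surfaces from
    images with momentum SGD, and counts are recovered by integrating the
    predicted density. Includes a synthetic scene generator with exact dot
    labels so the whole pipeline can be exercised without field data, plus
    MAE/RMSE evaluation and an architecture-by-batch-size comparison harness.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    png,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    igraph,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
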