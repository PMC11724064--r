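Package: leafhair
Title: Automated Leaf-Hair Coverage Quantification from Leaf-Disc Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies abaxial leaf-hair (trichome) coverage on 1-cm leaf-disc
    photomicrographs by slicing each image into a fixed grid of tiles and
    running a two-stage cascade of binary residual convolutional networks:
    stage one separates agar background from leaf tissue, stage two separates
    hairy from hairless leaf tiles. Reports the percentage of leaf area
    covered with hair, renders annotated slice maps, and writes batch CSV
    tables. Includes the full training harness (separable-convolution
    residual classifier, Adam optimiser, per-epoch checkpointing and
    train/validation-gap epoch selection), a synthetic leaf-disc generator
    with per-tile ground truth for end-to-end testing, and inter-rater
    agreement statistics (Pearson correlation, RMSE, signed error) for
    comparing automated output with human raters.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    EBImage,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    stats,
    utils,
    withr
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    MASS,
    jsonlite,
    optparse
Config/testthat/edition: 3
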