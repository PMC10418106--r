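Package: dispersr
Title: Dispersal Distance Estimation from Georeferenced SNP Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Estimates the mean per-generation dispersal distance (sigma) of a
    population from single-nucleotide polymorphism genotypes and the geographic
    coordinates of the sampled individuals. Provides a continuous-space
    individual-based forward simulator for generating training data under
    isolation by distance, a pairwise convolutional neural network that
    performs feature extraction on pairs of genotypes together with their
    geographic separation (with an optional gradient-gating strategy that
    restricts extractor-weight gradients to a random subset of pairs), a
    classical Rousset regression baseline that converts the slope of genetic
    differentiation on log geographic distance into a dispersal estimate, and
    an evaluation harness reporting relative and squared error metrics over
    held-out simulations. Includes VCF import, coordinate projection,
    sampling-scheme matching, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    optparse,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
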