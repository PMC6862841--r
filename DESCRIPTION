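Package: canopysel
Title: Canopy-Coverage Based Selection Experiments for Early-Stage Soybean Breeding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for image-based selection experiments in early-generation
    soybean breeding. Extracts plot-level canopy coverage from RGB imagery
    using the Excess Green index with Otsu thresholding and aggregates it to
    average canopy coverage (ACC); builds pedigree-based additive relationship
    matrices; fits single-trait animal models by Gibbs sampling with an
    optional field-correlation residual structure to obtain breeding values
    and narrow-sense heritabilities; performs truncation selection with
    overlap accounting and predicted-response calculations; and evaluates
    multi-location yield trials by restricted maximum likelihood with adjusted
    genotype means and category comparisons. A synthetic-data generator with
    known ground truth (pedigrees, breeding values, field trials, plot images)
    supports validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    Matrix,
    Rcpp,
    png,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    lme4,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
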