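Package: deltarad
Title: Delta-Radiomics of Daily Cone-Beam CT for Genitourinary Toxicity Modeling
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tested pipeline for longitudinal (delta) radiomics of daily
    cone-beam CT of the prostate: phantom cohort simulation, NRRD volume I/O,
    isotropic resampling, gold-fiducial streak-artifact removal, Collewet
    3-sigma re-segmentation, uniform and Lloyd-Max gray-level quantization,
    3D texture features (GLCM, GLRLM, GLSZM, NGTDM) plus first-order and
    volume-normalized features, biologically-effective-dose binning of
    per-fraction feature changes, CTCAE/IPSS endpoint labeling, and
    random-forest Gini feature selection with bootstrap leave-one-out
    validated logistic models.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    digest,
    yaml,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
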