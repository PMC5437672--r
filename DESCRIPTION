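Package: periradiomics
Title: Intratumoral and Peritumoral DCE-MRI Radiomics for Treatment
    Response Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A pipeline for predicting pathological complete response to
    neoadjuvant chemotherapy from pretreatment dynamic contrast-enhanced
    breast MRI. Computes voxel-wise texture maps (Laws energy measures,
    Gabor filter banks, Haralick gray-level co-occurrence statistics, and
    co-occurrence of local anisotropic gradient orientations) inside the
    tumor and in a peritumoral ring, fits the Tofts pharmacokinetic model
    as a physiological baseline, aggregates first-order statistics into a
    patient-by-feature table, discovers response-associated features with
    an iterated cross-validated minimum-redundancy maximum-relevance
    protocol, validates them by subsampled consensus clustering, and
    evaluates five standard classifiers under repeated cross-validation
    and holdout testing. Includes a deterministic digital-phantom
    generator so the full pipeline can be exercised on synthetic cohorts.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    e1071,
    withr,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    pROC,
    RNifti,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
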