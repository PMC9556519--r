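Package: hybridqc
Title: Hybrid Quality Control for Large Diffusion MRI Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for scalable quality control (QC) of diffusion MRI
    datasets using a hybrid paradigm: a small gold-standard set of expert
    ratings is amplified through calibrated community-science ratings and
    automated data-quality metrics via gradient-boosted voting ensembles,
    and distilled into a 3D convolutional QC classifier with
    integrated-gradients interpretation. Includes inter-rater reliability
    statistics (quadratic-weighted kappa, ICC3/ICC3k), leave-site-out
    generalization experiments, QC-cutoff sensitivity analysis of
    downstream age prediction (median imputation, ComBat-style site
    harmonization), and synthetic cohort generators that emulate the
    statistical structure of multi-site pediatric dMRI studies so that
    every pipeline stage is testable without data downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    xgboost,
    RNifti,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    sva,
    optparse
Config/testthat/edition: 3
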