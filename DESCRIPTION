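Package: fcadapt
Title: Domain Adaptation for Multi-Site Functional-Connectivity Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Semi-supervised variational autoencoder with maximum mean
    discrepancy (VAE-MMD) domain adaptation for three-way diagnostic
    classification (control, autism, Asperger) from multi-site resting-state
    functional-connectivity features. Includes Pearson-correlation feature
    extraction from ROI time series, empirical-Bayes ComBat harmonization of
    site effects, transfer learning from control-only auxiliary cohorts,
    SVM and MLP baselines, evaluation metrics (accuracy, F1, latent-space
    Gaussian KL divergence, t-SNE embedding), permutation-based feature
    importance with FDR control, and a synthetic multi-site cohort generator
    with known ground truth for offline validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    e1071
Suggests:
    testthat (>= 3.0.0),
    withr,
    sva
Config/testthat/edition: 3
RoxygenNote: 7.3.3
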