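Package: aslboost
Title: ASL-Guided Dose-Painting Simulation and Plan Evaluation for Brain
    Radiotherapy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to study simultaneous integrated boost (SIB) dose painting
    guided by arterial spin labeling (ASL) perfusion MRI in brain
    radiotherapy, with non-enhancing low-grade glioma as the motivating
    setting.  Provides a seeded digital brain phantom with a hyper-perfused
    tumour core, closed-form single-delay CBF quantification, relative-CBF
    threshold segmentation of the boost target, margin-based GTV/CTV/PTV
    structure derivation built on an exact anisotropic Euclidean distance
    transform, a simplified Gaussian-penumbra dose model for conventional and
    dose-painted plans, and DVH-based plan evaluation (D2%, D98%, D50%,
    Dmean, Dmax, D0.1cc, coverage, conformity and homogeneity indices) with
    organ-at-risk constraint checking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    RNifti,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
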