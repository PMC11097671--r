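Package: cbgrad
Title: Cerebellar Functional Gradients and Early Social-Emotional Outcomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: An end-to-end, testable pipeline for studying how the functional
    organization of the neonatal cerebellum relates to toddler social-emotional
    development. Provides motion-based volume censoring and scan-level quality
    control, voxel-wise Pearson functional connectivity, estimation of
    functional gradients by principal component analysis of the group
    connections-by-subjects matrix, covariate-adjusted linear-model association
    of gradient coefficients and regional volumes with outcome t-scores under
    Benjamini-Hochberg false-discovery-rate correction, and leakage-safe
    10-fold cross-validated outcome prediction with permutation-test inference.
    A synthetic-cohort generator with planted ground truth emulates the study's
    data structure so every stage can be validated without access to real
    neuroimaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    MASS,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
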