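Package: crorigin
Title: Origin Discrimination of Codonopsis Radix from Untargeted
    Metabolomics Feature Tables
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for authenticating the botanical origin of Codonopsis
    Radix (Dangshen) from untargeted LC-MS metabolomics data. Provides
    molecular-formula parsing and ESI adduct m/z arithmetic with ppm-error
    peak-to-database annotation, a synthetic cohort generator with planted
    differential metabolites for method development, percentile
    normalization and frequency filtering, one-way ANOVA plus fold-change
    differential screening with hierarchical clustering, a reference-
    normalized peak-area ratio cascade classifier, and chemometric models
    (PCA, NIPALS PLS-DA with R2Y/Q2Y/VIP, LDA, and a momentum-backprop
    neural network) with leave-one-out cross-validation, confidence
    measures and an external-validation workflow.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    MASS,
    jsonlite,
    stats,
    utils
Suggests:
    mixOmics,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
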