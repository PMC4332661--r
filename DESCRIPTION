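Package: cortsep
Title: Group Separability of Interregional Cortical Thickness Correlations
Version: 0.1.0
Authors@R: person("Maintainer", "Cortsep", email = "maintainer@cortsep.org", role = c("aut", "cre"))
Description: Tools for structural-covariance group comparison of cortical
    thickness tables: cohort-level interregional Pearson correlation matrices,
    selection of the region pairs with the largest cross-cohort correlation
    differences, resampled subset-of-six feature vectors, minimal-spanning-tree
    (Friedman-Rafsky) estimation of the Henze-Penrose divergence as a
    separability score, and sparsity-constrained linear classification under
    overlapping and subject-disjoint train/test protocols with bootstrap ROC
    evaluation. Includes a synthetic two-cohort generator with planted
    hub-correlation structure so the full pipeline is testable without MRI data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    glmnet,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml,
    igraph,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
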