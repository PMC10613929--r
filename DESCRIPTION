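Package: moephen
Title: Outcome-Driven Mixture-of-Experts Phenotyping for Clinical Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Joint discovery of patient phenotypes and in-hospital mortality
    risk with a deep mixture-of-experts model for two-tier tabular cohorts.
    A selector network over pre-treatment (presentation) features produces
    soft phenotype memberships (gates) and a pass-through representation;
    expert networks over the pass-through plus treatment-time features
    produce per-expert risks that are combined by a weighted vote. Includes
    an L2 gating penalty controlling expert utilisation, stratified
    cross-validation with pairwise adjusted-Rand-index stability selection
    followed by AUROC selection over an L2 penalty grid, Brier score
    decomposition, exact Clopper-Pearson binomial intervals for per-cluster
    mortality tables, ternary latent-space projections with local
    AUROC/AUPRC heatmaps, and a synthetic cardiogenic-shock-like cohort
    generator with planted subgroups and an exact risk oracle.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    ggplot2,
    jsonlite,
    stats,
    utils
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
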