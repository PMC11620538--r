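Package: mediomics
Title: Multi-Omic Mediation Analysis for Environmental Health
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for crossing three mediation strategies (high-dimensional
    penalized mediation, mediation with latent factors, and latent-cluster
    quasi-mediation) with three multi-omic integration stages (early,
    intermediate, late) in environmental-health studies that relate a
    continuous exposure to a health outcome through several omics layers.
    Includes cohort-aware preprocessing (within-cohort scaling, covariate
    residualization), total-effect estimation with forward covariate
    selection, fixed-effects meta-analysis and robustness-value sensitivity
    analysis, meet-in-the-middle feature screening with a sure-independence
    budget, distribution-of-the-product confidence intervals for indirect
    effects, joint-and-individual variance decomposition with permutation
    rank selection, an EM algorithm for latent-unknown-cluster models, and
    seeded generators of synthetic multi-omic studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    glmnet,
    nnet,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    metafor,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
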