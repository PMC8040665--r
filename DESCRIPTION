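Package: immunosig
Title: Multicohort Analysis of Chronic-Inflammation Immune Signatures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for multicohort systems-immunology analysis of
    chronic-inflammation signatures: per-cohort standard-score normalization
    and multiple linear regression with permutation-derived coefficient
    p-values and Storey q-value feature selection, functional-domain
    classification with cross-cohort overlap, hierarchical clustering with
    gap-statistic model selection and hypergeometric enrichment, two-class
    paired significance analysis of microarrays (SAM) with sign-flip
    permutation FDR for pre/post treatment change, and longitudinal Spearman
    correlation-network topology over immune signaling nodes (hubs,
    bottlenecks, modularity communities, permutation robustness). Includes a
    synthetic-data generator that emulates three cohorts (aging, HIV, HCV)
    with planted driver effects, planted correlation blocks, and longitudinal
    treatment trajectories, so the whole pipeline runs end-to-end without
    external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    cluster,
    mclust
Config/testthat/edition: 3
RoxygenNote: 7.3.3
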