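Package: crtphenomap
Title: Topological Phenogrouping and Risk Stratification for Cardiac
    Resynchronization Therapy Upgrade Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Builds Mapper-style topological patient-similarity networks
    from pre-upgrade clinical features of cardiac resynchronization
    therapy (CRT) upgrade candidates, delineates low-, intermediate-,
    and high-risk phenogroups by Louvain community detection followed by
    survival-guided merging, runs the accompanying survival analyses
    (Kaplan-Meier, log-rank, Cox proportional hazards, subgroup forest),
    and trains a nested cross-validated multi-class classifier ensemble
    that assigns new patients to the phenogroups.  A synthetic cohort
    generator with planted phenogroup structure and proportional-hazards
    survival makes the whole pipeline testable end to end without access
    to any patient-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    igraph,
    jsonlite,
    nnet,
    ranger,
    e1071,
    xgboost,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust,
    ggplot2
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
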