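Package: hcmtax
Title: Tree-Structured Taxonomy of Left-Ventricular Morphology in
    Hypertrophic Cardiomyopathy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Statistical shape analysis of the hypertrophic-cardiomyopathy
    left ventricle on a shared template mesh. Generates seeded synthetic
    cohorts of per-vertex wall-thickness maps with genotype-dependent
    regional effects, branch-structured morphological archetypes, polygenic
    scores and survival; computes vertex-wise covariate-adjusted association
    maps with permutation (max-T) or FDR multiplicity correction; learns a
    tree-structured morphology taxonomy by reversed graph embedding
    (DDRtree) with branch extraction and bootstrap stability; projects
    external patients onto the fitted tree via random-forest coordinate
    regression with nearest-neighbour branch labelling, trustworthiness and
    cohort-consistency diagnostics; clusters clinical feature tables into
    phenogroups; and overlays genotype probability, polygenic-score class
    and survival (Cox, Kaplan-Meier, cumulative hazard) on tree coordinates.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    S4Vectors,
    SummarizedExperiment,
    survival,
    cluster,
    randomForest,
    mclust,
    glmnet,
    data.table,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
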