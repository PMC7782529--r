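Package: metallonet
Title: Metal-Binding Protein Network Analysis for Parkinson's Disease Biomarkers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Systems-biology pipeline linking cellular metals to Parkinson's
    disease through their binding proteins. Groups metalloproteins by metal
    cofactor, builds first-neighbor metal protein networks from a reference
    interactome, tests their biological plausibility by principal component
    analysis of topological parameters against Erdos-Renyi and pathway
    networks, extracts cohesive protein hubs by greedy cohesiveness
    optimization, scores protein-disease association by pointwise mutual
    information over an abstract corpus, combines per-dataset differential
    expression by Fisher's method with location-scale batch merging,
    evaluates hubs as classifier feature panels under repeated stratified
    cross-validation, and computes cohort biomarker statistics (summary
    t-tests, 2^-ddCt relative expression, hypergeometric enrichment,
    correlation interdependency). A synthetic-data module emulates every
    input so the full pipeline runs offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    cluster,
    MASS,
    class,
    e1071,
    rpart,
    randomForest,
    glmnet,
    xgboost
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
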