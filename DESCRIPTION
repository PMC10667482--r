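Package: microconfig
Title: Gut Microbiota Configuration Analysis for Inflammatory Disease Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for comparative genus-level 16S gut-microbiome analysis in
    case-control cohorts: prevalence filtering and relative-abundance
    transforms, Bray-Curtis ordination (PCoA) with a median-centroid distance
    statistic, PERMANOVA with confounder adjustment, co-abundance group (CAG)
    detection by Ward-D2 clustering of genus Spearman correlations,
    within-group stratification of patients into normal-like versus
    Crohn's-like microbiota configurations, random-forest configuration
    classification, covariate (drug/diet) screening by logistic regression,
    Kendall-tau dietary pattern analysis, and compositionality-corrected
    (permutation-renormalisation) genus-inflammatory-marker association.
    Includes a synthetic cohort generator with planted community structure so
    the whole pipeline is testable without sequence data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vegan,
    permute,
    cluster,
    randomForest,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    glmnet,
    withr,
    optparse
Config/testthat/edition: 3
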