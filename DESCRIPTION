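Package: cytopredict
Title: Dissecting and Predicting Stimulated Cytokine Responses from Genetic and Environmental Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A machine-learning pipeline for dissecting and predicting
    stimulated-cytokine responses from genotype dosages, biological and
    environmental covariates. Implements leakage-controlled clumping and
    thresholding (C+T) feature selection, univariate and canonical-correlation
    multivariate GWAS on residualized inverse-rank-normalized traits, exact
    Hardy-Weinberg variant QC, SoftImpute matrix-completion phenotype
    imputation with lambda-grid tuning, immunotype discovery via hierarchical
    clustering with silhouette and gap-statistic model selection, nested
    cross-validated model benchmarking with permutation feature importance,
    Friedman/Conover multi-model comparison, and polygenic-score association
    testing against a permutation null. A synthetic cohort generator with
    LD-block genotype structure and recorded ground truth makes every stage
    testable without access to individual-level cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    glmnet,
    ranger,
    xgboost,
    cluster,
    jsonlite,
    withr,
    vcfR
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
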