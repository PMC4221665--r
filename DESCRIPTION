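Package: MorphoScreen
Title: Detection of Gene-Deletion Strains Beyond Natural Morphological Variation in Yeast
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantifies morphological variance in yeast strain populations
    profiled with CalMorph-style high-dimensional morphometry and detects
    gene-deletion strains whose multivariate morphology lies beyond the
    variation spanned by natural isolates. Trait values are normalized to
    Wald Z-scores through family-specific generalized linear models (gamma,
    beta, overdispersed binomial, and Lowess-uncoupled coefficients of
    variation), strains are ranked by Mahalanobis distance from the
    wild-type replicate center, population broadness is compared through
    principal-component equiprobability ellipses, outlying ("heteroclite")
    strains are detected by a family-wise error-controlled one-sample test
    per principal component, and gene-ontology associations are assessed by
    nested-model MANOVA. Includes a seeded synthetic-data generator that
    emulates the replicate structure of the assay with planted outlier
    strains for power and calibration studies.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    mgcv,
    withr,
    rlang
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
biocViews: Software, StatisticalMethod, CellBiology, Phenotype
RoxygenNote: 7.3.3
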