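Package: famlong
Title: Family-Based Longevity Scoring, Growth-Curve Change Phenotypes, and
    Kinship Heritability
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for family studies of exceptional longevity and healthy
    aging. Implements sibship-level longevity selection scoring from life
    tables (survival exceptionality with a living-sib bonus), pedigree
    kinship computation, random-coefficient (growth-curve) estimation of
    individual longitudinal change with empirical-Bayes shrinkage versus
    naive two-visit OLS slopes, kinship-based REML heritability of
    cross-sectional and slope phenotypes, and gene-dropping simulation of
    rare lineage-specific variants with per-family variance-component
    linkage LOD scores, heterogeneity LOD (HLOD) aggregation, and a
    single-variant association comparator. A seeded synthetic-data module
    generates two-generation sibship/offspring pedigrees, life-table
    lifespans, and two-visit phenotypes with known heritable intercept and
    slope structure so that every stage can be exercised and validated
    without restricted cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    lme4,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
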