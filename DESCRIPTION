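Package: sexmetab
Title: Sex-Stratified Metabolite-Brain Association Analysis
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for detecting sex differences in the association between
    blood metabolites and structural brain phenotypes in neurodegeneration
    cohorts. Implements targeted and NMR-style metabolomics quality control
    (plate normalization, replicate CV/ICC filters, left-censored imputation,
    winsorized z-scaling, medication residualization, Mahalanobis outlier
    screening), PLS-DA reduction of brain segment volumes against diagnosis,
    weighted correlation network modules of metabolites with topological
    overlap and dynamic tree cut, eigen-metabolite summaries, sex-stratified
    linear models, heterogeneity (Z-diff) and inverse-variance overall
    (Z-overall) tests, a two-fold screening procedure and a criterion-based
    classification of associations, with Bonferroni and effective-number-of-
    tests corrections. Includes a synthetic cohort generator with known
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
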