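Package: empdpanel
Title: Immunohistochemistry Marker Panel Analysis for Extramammary Paget
    Disease Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Semi-quantitative immunohistochemistry (IHC) analysis of a
    targetable-marker panel (B7 family, cancer/testis antigens, antigen
    presenting machinery, cytokeratins) across tumor components of an
    extramammary Paget disease cohort. Provides a SummarizedExperiment-based
    cohort container with CSV import/export and validation, composite
    percent-by-intensity scoring with dual-block averaging, marker and
    tumor-infiltrating-lymphocyte summaries, coexpression-category
    tabulation, permutation inference for group differences in percent
    positive with Benjamini-Hochberg false discovery rate control,
    component/resection concordance statistics (Spearman, cosine, Kendall
    tau-b), complete-linkage Manhattan clustering with missing-value
    handling, a configurable synthetic-cohort generator, and an end-to-end
    pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
biocViews: ImmunoOncology, Clustering, StatisticalMethod
RoxygenNote: 7.3.3
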