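Package: tilspatial
Title: Spatial Proximity and Cohort Statistics for Tumor-Infiltrating
    Lymphocytes in Multiplex Immunohistochemistry
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Quantifies tumor-infiltrating lymphocyte (TIL) phenotypes from
    segmented multiplex immunohistochemistry (mIHC) cell tables and
    characterises their spatial organisation within imaged fields. Implements
    marker-based phenotype gating, per-field infiltration densities as ratios
    to DAPI, the bivariate (cross-type) Ripley K function with translation
    edge correction, fixed-radius neighbourhood proximity densities,
    pathological response classification (MPR/pCR) from viable-tumor
    percentages, tertiary lymphoid structure densities, and the cohort
    statistical layer (rank tests, two-way ANOVA with multiple comparisons,
    Kaplan-Meier survival with median and maximally selected cutpoints). A
    synthetic-data generator produces point-pattern fields and paired
    two-arm cohorts with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    survival,
    withr,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'conditions.R'
    'AllClasses.R'
    'RcppExports.R'
    'accessors.R'
    'io.R'
    'response.R'
    'phenotype.R'
    'simulate.R'
    'fixtures.R'
    'spatial.R'
    'stats.R'
    'survstats.R'
    'tilspatial-package.R'
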