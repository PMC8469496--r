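Package: CPDscreen
Title: Cell Population Data Discriminants for Screening Haematological
    Neoplasms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Rule-based screening of haematological disorders from
    leukocyte cell population data (CPD / VCS parameters) reported by
    volume-conductivity-scatter full blood count analysers. Implements a
    published composite neoplastic score
    (SD-V-NE x MN-UMALS-LY x SD-AL2-MO) / MN-C-NE, a single-parameter
    reactive-case discriminant (MN-AL2-NE), advisory leukaemia-subtype
    flags, and the staged decision cascade combining them, together with
    the calibration pipeline that derives such discriminants from any
    labelled CPD cohort (hypothesis-test screening, ROC analysis with
    DeLong confidence intervals, Youden cutoff selection), clinical
    diagnostic-accuracy statistics with continuity-corrected Wilson
    confidence intervals, and a seeded synthetic-cohort simulator for
    end-to-end testing without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.3),
    SummarizedExperiment
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    pROC,
    car,
    nortest,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'CPDscreen-package.R'
    'calibration.R'
    'cohort.R'
    'diagnostics.R'
    'io.R'
    'parameters.R'
    'rules.R'
    'screening.R'
    'simulate.R'
    'utils.R'
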