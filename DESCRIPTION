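Package: itemnr
Title: Item Nonresponse Factors, Selection-Aware GWAS and Heckman Correction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying participant-selected item nonresponse
    ("Prefer not to answer" and "I don't know") in survey-based cohorts and
    its consequences for genome-wide association studies. Provides a
    synthetic-cohort simulator with a probit selection (MNAR/collider)
    mechanism and full ground truth; maximum-likelihood tetrachoric and
    polychoric correlation estimation; a factor-construction pipeline
    (single-factor EFA, residual clustering, branch collapsing, bifactor
    EFA/CFA, empirical-Bayes style factor scores); a linear-regression GWAS
    engine with QC filters and LD clumping; the two-step Heckman correction
    for informative missingness via the inverse Mills ratio; and logistic
    prediction of follow-up nonresponse with Cox-Snell, Nagelkerke and
    McKelvey-Zavoina pseudo-R2 measures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    MASS
Suggests:
    testthat (>= 3.0.0),
    mvtnorm,
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
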