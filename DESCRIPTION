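Package: endoprs
Title: Polygenic Risk Score Analysis for Endometriosis Case-Control Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for small-panel polygenic risk score (PRS)
    analysis of endometriosis in case-control cohorts: genotype quality
    control (Hardy-Weinberg exact test, allele-swap detection, duplicate
    concordance, within-cohort mean imputation), weighted-allele PRS
    computation with effect-allele harmonization and within-stratum
    standardization, ICD-10 N80 phenotype classification with severity-ranked
    subtype collapsing, and case-control evaluation (odds ratio per standard
    deviation, AUC, Nagelkerke's R-squared, decile odds ratios). Includes a
    synthetic cohort generator with a calibrated logistic disease model on
    the standardized PRS, so every stage of the analysis can be verified
    against known ground truth without access to protected registry data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
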