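Package: hydradjust
Title: Hydration Adjustment of Spot-Urine Biomonitoring Data
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for adjusting spot-urine biomarker concentrations for
    hydration (urinary dilution) variation.  Implements creatinine,
    osmolality (Levine-Fahy form), excretion-rate, bodyweight-normalised
    excretion-rate and analyte-specific urinary-flow-rate power-law
    (Araki) adjustments; derives analyte-specific flow-rate exponents by
    grid search under two optimisation criteria (minimal residual
    correlation with urinary flow rate, maximal correlation with blood
    concentration); applies an eligibility cascade (albuminuria,
    diabetes, chronic kidney disease via CKD-EPI or Bedside Schwartz
    eGFR, analytical non-detects) with a full audit trail; and assesses
    method performance with ln-scale Pearson correlations, Williams's
    test for dependent correlations and compact letter displays.  A
    synthetic-cohort generator reproduces the log-linear dilution
    structure the analysis assumes, so the whole pipeline is testable
    without access to survey microdata.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    MASS,
    foreign,
    knitr
Config/testthat/edition: 3
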