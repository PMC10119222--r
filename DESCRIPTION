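Package: grp4risk
Title: Molecular Risk Stratification for Group 4 Medulloblastoma
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Risk-stratification toolkit for Group 4 medulloblastoma
    (MB_Grp4). Calls whole-chromosome aberrations (WCA) and isochromosome
    17q from arm-level copy-number input, re-derives prognostic k-of-set
    WCA signatures by exhaustive search scored on progression-free
    survival, encodes the three-tier risk scheme that combines metastatic
    stage, WCA group and methylation subgroup 7, and provides the survival
    machinery used to validate schemes: Kaplan-Meier estimation, log-rank
    tests, Cox proportional-hazards fits with backwards selection and
    Schoenfeld diagnostics, Harrell's c-index with bootstrap optimism
    correction, and calibration at a fixed horizon. A synthetic-cohort
    generator reproduces the clinical, cytogenetic and survival structure
    the analysis assumes, so the full pipeline is testable without
    patient-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    survival,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
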