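Package: dilirules
Title: Risk-Rule and Docking-Score Analysis for Drug-Induced Liver Injury
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing drug-induced liver injury (DILI) risk in
    oral-drug cohorts: severity grading from label endpoints, exact 2x2
    association statistics (odds ratios, Woolf confidence intervals,
    Fisher's exact test, positive predictive value), association scans
    over the WHO Anatomical Therapeutic Chemical (ATC) hierarchy, a
    threshold-conjunction risk-rule engine combining molecular weight,
    lipophilicity, defined daily dose and extent of liver metabolism
    (the "rule of four"), and normalization plus group statistics for
    drug-by-protein docking-score matrices. A synthetic-cohort generator
    with planted effect sizes makes every stage testable end to end
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
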