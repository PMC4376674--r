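Package: vteprophy
Title: Decision-Tree Cost-Effectiveness Analysis of VTE Prophylaxis in
    Medical Inpatients
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Decision-analytic evaluation of pharmacological venous
    thromboembolism (VTE) prophylaxis for acutely ill medical inpatients
    from a US healthcare-system perspective. Implements a 30-day
    decision-tree model comparing low-molecular-weight heparin,
    unfractionated heparin and no prophylaxis; computes expected deaths and
    costs for a hypothetical cohort, incremental cost-effectiveness ratios,
    one-way (threshold) sensitivity analyses, probabilistic sensitivity
    analysis with beta/gamma parameter distributions and
    cost-effectiveness acceptability curves; and extrapolates cohort
    results to the US national inpatient population through an
    eligibility funnel. Includes a patient-level microsimulation twin of
    the tree and a synthetic admission-record generator for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
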