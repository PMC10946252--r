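Package: osipbpk
Title: Whole-Body PBPK/PD Modeling of Osimertinib Across Ethnic Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Whole-body physiologically based pharmacokinetic (PBPK) model of
    the third-generation EGFR inhibitor osimertinib, with Rodgers-Rowland
    tissue partitioning, six-enzyme hepatic clearance including CYP3A4
    auto-inhibition and auto-induction, renal filtration clearance, and an
    irreversible EGFR T790M/L858R pulmonary target-occupancy pharmacodynamic
    model. Builds reference physiologies for Caucasian, Japanese and Chinese
    healthy and NSCLC populations, samples seeded virtual populations with
    log-normal inter-subject variability, computes non-compartmental metrics
    and geometric summary statistics, runs local sensitivity analyses, and
    evaluates dosing regimens against plasma trough and pulmonary inhibition
    thresholds.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    deSolve,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
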