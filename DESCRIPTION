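Package: aortasurv
Title: Multi-State Surveillance Modelling After Elective Aortic Surgery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for evaluating post-operative surveillance schedules after
    elective (non-emergent) open or endovascular aortic surgery. Provides a
    patient-cohort data model with an eligibility cascade and derivation of
    composite aortic-event outcomes, a from-scratch Kaplan-Meier product-limit
    estimator with Greenwood log(-log) confidence bands and risk tables, a
    discrete-time non-homogeneous four-state Markov chain (healthy,
    complication, reintervention, death) estimated from interval event data,
    exact occupancy propagation and seeded cohort simulation, and
    number-needed-to-harm summaries for skipped follow-up visits. A seeded
    synthetic-cohort generator with known transition structure supports
    testing and parameter-recovery studies without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    survival,
    withr,
    optparse
Config/testthat/edition: 3
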