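Package: turtledose
Title: Dose-Response Models Linking Ingested Plastic Debris to Sea Turtle Mortality
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for estimating the relationship between the load of ingested
    plastic debris and the probability of death in sea turtles from necropsy and
    stranding records. Implements a negative binomial regression of debris counts
    on cause of death with AIC model selection and multiplicity-corrected pairwise
    contrasts; a Monte Carlo estimator for logistic dose-response models with
    interval-valued (partially observed) mortality outcomes; prediction and
    inversion of the fitted mortality curve with uncertainty envelopes, including
    cohort-averaged 50%-mortality loads; and a presence/absence logistic model for
    stranding-register records with examination-level detection effects. A
    synthetic-data generator emulating the statistical structure of necropsy
    cohorts and stranding registers supports testing and parameter-recovery
    studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    MASS,
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
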