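Package: myelotitr
Title: Myelosuppression PK-PD Modelling and Model-Based Adaptive Dose Titration
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Population pharmacokinetic-pharmacodynamic modelling of
    chemotherapy-induced myelosuppression (two-compartment disposition
    coupled to five-compartment transit models with feedback for
    neutrophil and platelet counts), together with the model-based
    machinery of an adaptive phase-I design: empirical-Bayes individual
    fitting, simulation-based individual dose titration, cohort
    starting-dose estimation, and a virtual trial engine. Includes
    packaged clinical summary fixtures, a synthetic-study generator
    emulating the trial's sampling design, and a NONMEM-style dataset
    reader/writer.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
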