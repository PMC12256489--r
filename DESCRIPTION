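Package: tdmcea
Title: Cost-Effectiveness of Therapeutic Drug Monitoring in Pediatric Epilepsy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Decision-analytic evaluation of therapeutic drug monitoring (TDM)
    of perampanel in children with epilepsy. Provides clinical-outcome
    classification and cohort statistics (responder and seizure-free rates,
    proportional-odds ordinal regression), a two-arm four-state Markov cohort
    model with an adverse-event layer and odds-ratio based arm derivation,
    incremental cost-effectiveness (ICER, dominance, net monetary benefit),
    one-way (tornado) and probabilistic sensitivity analyses with a
    cost-effectiveness acceptability curve, scenario analyses over alternative
    time horizons and monitoring policies, and a synthetic patient-cohort
    generator so every stage of the pipeline can be exercised end to end
    without access to the original patient records.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    MASS,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
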