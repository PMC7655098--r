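Package: updatebias
Title: Valence-Dependent Belief Updating and Time to Relapse in Bipolar
    Disorder
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Scores the belief update (good news / bad news) task,
    constructs censored log-transformed time-in-euthymia outcomes, and
    fits the prognostic linear-model family used in prospective bipolar
    cohorts: ordinary least squares with standardized coefficients,
    case-resampling bootstrap intervals and variance-inflation
    diagnostics, exhaustive all-subsets BIC-weighted model averaging,
    and leave-one-out predictive validation. A synthetic-cohort
    generator with known ground truth makes the full pipeline testable
    without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    e1071,
    jsonlite,
    stats,
    utils
Suggests:
    car,
    nortest,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
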