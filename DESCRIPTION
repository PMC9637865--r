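Package: normdev
Title: Normative Modeling of Global Brain Features with Bayesian Deviation-Psychopathology Association
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Normative models of global white- and gray-matter brain features
    across development, fitted by Bayesian linear regression on age and sex with
    a cubic B-spline expansion of age and marginal-likelihood hyperparameter
    optimization (Powell search). Produces cross-validated per-subject deviation
    Z-scores, decomposes a cognitive battery (PCA general factor) and a
    psychopathology questionnaire (stability-resampled ICA domains plus a
    general-psychopathology proxy), and quantifies deviation-behavior
    associations with Bayesian linear models and Savage-Dickey density-ratio
    Bayes factors. Includes a synthetic cohort generator with known ground
    truth for calibration and parameter-recovery studies, and a configurable
    end-to-end pipeline with tabular and JSON reports.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    splines,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
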