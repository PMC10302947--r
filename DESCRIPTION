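Package: htncea
Title: Cost-Utility Modelling of Hypertension Prevention Strategies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A four-state Markov cohort model of the natural history of
    hypertension (normal, pre-hypertension, stage I, stage II), with
    regression from pre-hypertension to normal, three end-organ
    complications (acute myocardial infarction, stroke, end-stage renal
    disease) and complication-attributable mortality. Four prevention
    strategies (usual care, population-wide lifestyle modification,
    high-risk pharmacological prevention, and risk-score-guided
    personalized prevention) are evaluated by discounted cost-utility
    analysis: incremental cost-utility ratios, net monetary benefit,
    cost-effectiveness plane classification, and Monte-Carlo
    probabilistic sensitivity analysis with acceptability curves.
    Parameters are read from validated YAML configuration files carrying
    base-case values and Beta/Triangular uncertainty distributions; a
    synthetic-data module generates covariate profiles with known
    risk-score structure and closed-form toy models for verification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
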