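Package: dcekit
Title: Design and Analysis of Discrete Choice Experiments for Health Preferences
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for the full workflow of a stated-preference discrete
    choice experiment (DCE): effects coding of attribute levels, D-efficient
    blocked choice-set design by coordinate exchange, conditional
    (multinomial) logit, panel random-parameters (mixed) logit estimated by
    simulated maximum likelihood over Halton draws, latent-class conditional
    logit with a covariate-driven class-membership model, relative attribute
    importance, and scenario uptake simulation. Includes a synthetic
    respondent generator emulating a sexual-health risk-tool preference
    survey (415 respondents, six choice tasks each, opt-out alternative) for
    calibration and parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
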