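Package: telomod
Title: Bayesian Moderated Regression of Telomere Length and Adolescent
    Internalizing Symptoms
Version: 0.1.0
Authors@R:
    person("telomod", "maintainers", email = "telomod@example.org",
           role = c("aut", "cre"))
Description: Tools to study how the social environment moderates the
    association between relative telomere length (qPCR T/S ratio) and
    adolescent anxiety and depressive symptoms. Provides a synthetic
    cohort generator with multi-scale Likert instruments and matching
    qPCR plates, efficiency-corrected T/S quantification with standard
    curves and repeatability (ICC), psychometric scale scoring with
    reliability gating and chained-equations imputation, a conjugate
    Gibbs sampler for moderated linear regression with standard-normal
    coefficient priors, Savage-Dickey inclusion Bayes factors, highest
    density intervals and split-chain convergence diagnostics, and an
    end-to-end pipeline with parameter-recovery tooling.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    MASS
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    optparse
Config/testthat/edition: 3
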