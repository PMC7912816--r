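Package: trufflepath
Title: Path Analysis of Truffle Fruitbody Development Characters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for testing causal hypotheses about the development of
    hypogeous fruitbodies (truffles) with the d-separation method of path
    analysis. Causal models are specified as directed acyclic graphs over
    harvest characters (fruiting depth, fresh weight, shape index, spore
    maturity, harvesting date); the package constructs the Shipley basis
    set of conditional-independence claims, tests each claim by partial
    correlation or family-appropriate generalized regression, combines the
    claim probabilities into Fisher's C, and ranks competing models by
    small-sample-corrected AIC and Akaike weights. Structural equations of
    a selected model are fitted with generalized additive models and the
    contribution of each predictor is summarized as percent deviance
    explained under drop-term refits with frozen smoothing parameters. A
    partial least squares estimator predicts fruitbody fresh weight from
    caliper diameters. A synthetic-data generator draws harvest datasets
    from an explicit true causal model so that the whole pipeline can be
    exercised and calibrated without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    mgcv,
    jsonlite
Suggests:
    mixOmics,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
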