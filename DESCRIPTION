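Package: oblearn
Title: Observational Reversal Learning: Bayesian Behavioural Modelling and
    Single-Unit Prediction-Error Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for model-based analysis of observational reversal
    learning with single-neuron electrophysiology. Implements a generative
    model of a two-deck card-game task with probabilistic reversals and two
    observed players, a hierarchical grid Bayesian observer yielding
    trial-wise expected values, choice entropy and reward prediction errors,
    softmax choice modelling with maximum-likelihood temperature fitting,
    behavioural choice and choice-time regressions with lagged self/observed
    outcome structure, and a spike-train analysis engine: sliding-window
    firing-rate estimation, a nine-regressor trial GLM with observational
    prediction-error contrasts, cluster-based permutation inference,
    bootstrap response envelopes, and model-free early/late win comparisons.
    A synthetic-data module simulates complete cohorts (choices, choice
    times, inhomogeneous Poisson spike trains with planted coding schemes)
    so that every stage of the pipeline can be exercised and calibrated
    without access to clinical recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
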