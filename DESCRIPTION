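Package: bystanderRL
Title: Adaptive Reinforcement-Learning Bystander Experiments with Bayesian
    Response Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale computational pipeline for adaptive virtual-reality
    bystander experiments. A tabular Watkins' Q(lambda) agent with eligibility
    traces learns, across accumulating participant cohorts, which virtual-character
    actions (victim gaze, perpetrator gaze, bystander utterances) elicit helping
    interventions. Synthetic participants generated from a Bernoulli logistic model
    with subject effects replace human subjects, and the resulting datasets are
    analysed with the study's Bayesian models: Beta-Binomial logistic regressions
    of intervention counts on the realised proportion of random actions or on the
    learning-level factor, and a simplex-constrained Bernoulli logistic model of
    per-trial responses on action type. Includes posterior summaries, split-chain
    Rhat, posterior predictive simulation, point-biserial model checking and
    parameter-recovery calibration.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    rjags,
    coda,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
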