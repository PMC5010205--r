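Package: gonogo
Title: Go/NoGo Opponent Learning Models of Reward Uncertainty in the
    Basal Ganglia
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulates and analyses a family of basal-ganglia
    reinforcement-learning models in which the difference of Go and NoGo
    cortico-striatal synaptic weights (G - N) encodes the mean reward of
    an action and their sum (G + N) encodes the spread of its reward
    distribution.  Provides the actor-only (AU), generalized-AU,
    actor-critic (ACU) and opponent actor learning (OpAL) update rules,
    the dopamine-modulated generalized softmax choice rule with its
    mean/spread utility decomposition, closed-form stochastic fixed-point
    predictors, synthetic bandit environments (Gaussian bandits, a
    safe-versus-risky lever task, a three-option probabilistic selection
    task), and a simplex-based procedure for fitting choice-gain
    parameters to observed risky-choice fractions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
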