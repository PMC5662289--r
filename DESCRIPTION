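Package: obsirl
Title: Observational Learning of Hidden Reward Distributions by Inverse
    Reinforcement Learning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and model-based analysis of observational bandit
    learning, in which an observer infers the hidden outcome distributions of
    slot machines from another agent's choices alone. Implements an
    approximate inverse reinforcement learning observer (multiplicative
    posterior-mean belief updates), imitation learners with an inversion
    parameter and a counterfactual variant, and a preference-ranking learner;
    constrained maximum-likelihood fitting with multistart, BIC scoring,
    random-effects Bayesian model selection with exceedance probabilities,
    generate-and-recover confusion studies, trial-wise model signals
    (agent-referential expected value and KL belief updates) for use as
    regressors, and descriptive behavioral metrics (choice ratios, rank
    correlations, a social-information-integration index). Includes a
    synthetic-cohort generator emulating the two-condition
    (similar/dissimilar agent) session structure.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    graphics,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
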