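Package: reciprosim
Title: Simulation and Analysis of Reciprocal Social Influence Experiments
Version: 0.1.0
Authors@R:
    person("Repo", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Seeded simulation and analysis pipeline for a joint length-reproduction
    paradigm in which a human participant and an algorithmic partner (framed as a
    computer or a humanoid robot) exchange perceptual estimates and final decisions.
    Implements the partner agent's fully specified stochastic behavior (Gaussian
    estimate sampler, condition-dependent influence mixtures, transition schedules),
    a generative model of the human participant (Bayesian central-tendency observer
    with scalar variability, logit-linear influence policy, performance ratings),
    the behavioral indices of the paradigm (influence index, estimation error,
    regression index, distance-binned standardized influence), and the associated
    statistical contrasts (Wilcoxon tests with rank-based effect sizes, Spearman
    correlations, random-intercept mixed models) behind a reproducible,
    configuration-driven pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lme4,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
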