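Package: treequery
Title: Hierarchical Decision-Tree Query Task, Agents and Behavioral Analyses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis toolkit for a hierarchical perceptual
    decision-making task in which an agent searches for a target hidden at a
    leaf of a three-level binary decision tree by querying internal nodes for
    noisy motion evidence. Implements the task model (coherence- and
    direction-labelled nodes, Gaussian evidence pulses, query/error/target
    payoffs), an extrema-detection choice model with level-dependent collapsing
    criteria and its evidence-integration variant, maximum-likelihood fitting
    and model comparison, an exact discrete Bayesian belief engine with
    collider (explaining-away) inference after leaf errors, an approximately
    optimal Monte-Carlo rollout planner, myopic active-sensing policies
    (probability gain, information gain, impact), a confidence-based
    blame-assignment heuristic agent, and the behavioral analyses used to
    compare agents: transition statistics, action classification, blame
    statistics, logistic regressions and reward summaries. Includes synthetic
    session generators and parameter-recovery harnesses.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    Rcpp,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
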