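Package: aimaze
Title: Active Inference and Active Learning Agents in T-Maze Tasks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation of discrete-state partially observable Markov decision
    agents that select policies by minimising expected free energy. The policy
    value decomposes additively into a model-parameter information gain
    ("novelty", active learning), a hidden-state information gain ("salience",
    active inference) and an expected log-preference ("utility") term; policy
    and action selection are precision-controlled, and the observation model
    and initial-state prior are learned by Dirichlet count accumulation.
    Includes T-maze reward-learning and context-inference environments, a
    non-instrumental information-preference task, agent ablations, and batch
    experiment runners that reproduce the characteristic exploration
    phenotypes of each agent.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
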