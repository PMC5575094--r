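Package: normsim
Title: Aspiration Learning and the Emergence of Giving Norms in the
    Dictator Game
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Agent-based simulation of social-norm formation in the Dictator
    Game. Agents hold aspirations (expected donations) that are updated by a
    Bush-Mosteller style reinforcement-learning rule, habituate their own
    donations towards the donations they receive, and never donate more than
    the endowment minus their aspiration. Optional ingredients are a
    multiplicative trembling-hand perturbation of donations, inequity-averse
    agents capped at half the endowment, and obstinate free-riders that never
    update. The package provides the update rules, a population engine with
    random pairwise matching and a stationarity criterion based on the slope
    of the population-mean donation, replication and parameter-sweep drivers,
    and the summary statistics used to characterise the stationary state
    (binned donation/aspiration distributions, mean donation, and a
    Gini-based equality index).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    jsonlite,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
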