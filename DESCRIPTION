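Package: coevoPD
Title: Coevolution of Strategies and Link Weights in the Spatial
    Prisoner's Dilemma
Version: 1.0.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Asynchronous Monte Carlo simulator for the weak prisoner's
    dilemma on a periodic square lattice with Moore neighborhoods, in which
    game strategies and symmetric link weights evolve together.  A focal
    player's utility is the weight-multiplied sum of its pairwise payoffs;
    links towards neighbors that paid above the player's mean pairwise
    payoff are reinforced, those below punished, within hard weight bounds,
    and strategies spread by a utility-difference imitation rule.  Provides
    the compiled simulation kernel, observables (cooperation fraction,
    stationary averages, link-weight distributions, strategy snapshots),
    experiment drivers for amplitude sweeps, time courses, temptation
    sweeps and phase diagrams with extinction boundaries, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    png,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
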