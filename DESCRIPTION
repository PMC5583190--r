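Package: swarmresp
Title: Connectivity and Collective Responsiveness in Swarm and Consensus Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis toolkit for studying how the number of
    interacting neighbors controls the responsiveness of collectives. Provides
    a discrete-time Vicsek self-propelled-particle simulator in a periodic box
    with metric or topological (k-nearest-neighbor) interactions, estimators
    of the connected velocity-fluctuation correlation C(r) and the integrated
    correlation (susceptibility) chi, a predator-attack protocol measuring
    collective avoidance times, a linear threshold consensus model on static
    networks with pinned informed agents and its polarization speed, and an
    exact frequency-domain gain analysis of leader-follower linear consensus
    on arbitrary graphs, including low- and high-frequency expansions.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Matrix,
    igraph,
    deSolve,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
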