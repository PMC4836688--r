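Package: crowdguess
Title: Collective Color-Code Guessing Games on Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis of collective guessing games in which
    players placed on a k-regular interaction network collaboratively
    reconstruct a ten-position three-color code from partial private
    information and the proposals of their network neighbors. Provides an
    event-driven agent-based simulator with pluggable decision rules
    (majority, voter, random, Bayesian aggregation of neighbor signals, and
    empirically estimated transition tables), plain-text game-log
    input/output, descriptive performance metrics (accuracy trajectories,
    inter-proposal statistics, Hamming distances, information propagation
    from information sources), empirical transition-probability estimation,
    Bayesian-model parameter fitting by grid-search root-mean-square error,
    and matched-condition comparisons of decision rules.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    ggplot2,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
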