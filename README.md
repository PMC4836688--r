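# crowdguess

Simulation and analysis of **collective guessing games on networks**: a
group of players, each holding partial private information, collaboratively
reconstructs a hidden 10-position color code (red/blue/yellow) by repeatedly
proposing complete codes and watching the proposals of their network
neighbors. The package is aimed at researchers in collective behavior and
opinion dynamics who want a tested, reproducible pipeline for this class of
experiment: an agent-based simulator that emulates the experimental
protocol, canonical plain-text game logs, the descriptive statistics of
group performance and information propagation, and the decision model at
the core of the analysis.

## The model

Each player on a k-regular network (k = 4; ring lattice or degree-regular
random graph) sees 3 of the 10 positions of the common target at game
start; reveal sets jointly cover the code, making some nodes *sources* for
each position. Players propose complete codes at exponential inter-proposal
times during a 225 s game. The decision model treats every unknown position
independently: a neighbor showing color *x* is a signal with likelihood
ratio *s* = C′/C₀ (mismatching vs matching the truth), so after observing
counts (n_R, n_B, n_Y) the posterior weight of color *x* is s^(−n_x), and a
prior-odds parameter *a* multiplies the current color's weight by 1/a:

    P(X | A = X)  = 1 / (1 + a · Σ_{x≠X} s^(n_X − n_x))
    P(X | A ≠ X)  = 1 / (1 + s^(n_X − n_A)/a + Σ_{x∉{X,A}} s^(n_X − n_x))

*s* < 1 means the neighborhood outweighs one's own opinion; *a* < 1 is
inertia toward the current choice. The parameters are estimated from
empirical transition tables — P(X | n_X), stay and switch curves — by
grid-search RMSE. Benchmark update rules (majority, voter, random, and an
empirically estimated transition table) run under matched conditions for
comparison.

## Worked example

```r
library(crowdguess)

net   <- make_network(20, k = 4, topology = "random_regular", seed = 42)
setup <- make_game_setup(20, seed = 42)       # target + covering reveals
rule  <- decision_rule("bayesian", s = 0.57, a = 0.19)
log   <- simulate_game(setup, net, rule, seed = 42)
log
#> <guess_log> game01 [synthetic:bayesian]: 20 players on random_regular, 153 proposals in 225s

cv <- accuracy_curve(log)                     # p(t), 1 s grid
cv$p[nrow(cv)]                                # mean correct positions at 225 s
#> [1] 7.1
end_hamming(log)                              # mean pairwise final distance
#> [1] 3.88

# a four-game session in the first study session's topology order,
# then transition extraction and the two-parameter fit
logs   <- simulate_session(experiment_session_config(1), seed = 42)
events <- do.call(rbind, lapply(logs, extract_transitions))
fit    <- fit_two_param(transition_table(events))
fit
#> <fit_result> two-parameter model: s = 0.56, a = 0.18 (RMSE 0.0086 over 10 cells)
interproposal_fit(logs)
#> <exp_fit> rate b = 0.0394 /s (characteristic time 25.4 s, n = 536)
```

Reading the output: the group ends the game with 7.1 of 10 positions
correct on average while individual final codes still differ in ~3.9
positions; four games' worth of decisions (about 3,700 transition events)
already recover the generating parameters (0.57, 0.19) to within ±0.01.
The fitted inter-proposal rate sits slightly above the generating
0.036 /s because within-game intervals are truncated at the game end (see
the methods vignette).

The full pipeline is also available as four commands — `cmd_simulate()`,
`cmd_analyze()`, `cmd_fit()`, `cmd_compare()` — each writing CSV reports
plus a run manifest, with a thin CLI wrapper in `inst/cli/crowdguess.R`
and a demo session config in `inst/extdata/demo_session.yaml`.

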