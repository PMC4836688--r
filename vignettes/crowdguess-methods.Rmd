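---
title: "Models and methods behind crowdguess"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind crowdguess}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

```{r setup}
library(crowdguess)
```

## The game and its data

A group of $N$ players sits on the nodes of a simple, connected network in
which every node has degree $k$ (here $k = 4$). The group must reconstruct a
common *color code*: an ordered sequence of $L = 10$ positions, each colored
red (R), blue (B) or yellow (Y). At the start of a game each player privately
sees the true colors of 3 of the 10 positions; the reveal sets are random but
jointly cover the whole code, so every position has at least one *source*
node. During the 225 seconds of a game each player repeatedly submits
complete 10-position proposals and sees the latest proposals of her network
neighbors (and only those, and only after her own first complete guess).
At the end, a player scores 10 points for finishing, 100 per correct
position, and a 1000-point bonus for the full code.

The unit record is the *proposal*: `(player, time, code)`. A game log bundles
the proposals with the network edge list, the target code and the reveal
assignment; `write_game_log()` / `read_game_log()` serialize this as four
plain CSV tables with 1-based positions and times stored at full double
precision (17 significant digits), so a write–read–write cycle is
byte-identical.

## The synthetic experiment generator

The package ships an event-driven agent-based simulator
(`simulate_game()`, `simulate_session()`) that reproduces the statistical
structure of such sessions:

* **Networks** (`make_network()`): a ring lattice in which each node connects
  to the $k/2$ nearest nodes on each side, or a degree-regular random graph
  sampled uniformly and resampled until connected (cap 1000 tries). The ring
  is used for the "regular lattice" because the group sizes in play (17 and
  20) do not admit a $k = 4$ torus; this choice is an assumption, not a
  verified property of the original apparatus.
* **Setups** (`make_game_setup()`): the target is uniform over the $3^{10}$
  codes; reveal sets are drawn uniformly subject only to the coverage
  constraint (rejection sampling).
* **Schedules**: each player proposes at exponential waiting times with rate
  $b = 0.036\,\mathrm{s^{-1}}$ (the rate fitted to the observed sessions),
  truncated at 225 s. Event times are continuous; ties across players are
  broken by drawing order and zero inter-proposal intervals are resampled so
  per-player times are strictly increasing.
* **Decisions**: the first proposal fills revealed positions with their true
  colors and the rest uniformly (the rule applied with no neighbor
  information). Every later proposal keeps revealed positions at the truth —
  by default with probability 1; a `fidelity` parameter below 1 reproduces
  the small observed drift — and redraws every unknown position
  independently (positions are treated as independent throughout) using the
  game's decision rule and the neighbors' current codes. Neighbors that have
  not proposed yet contribute nothing to the neighbor counts.

All randomness flows from one explicit integer seed per game or session; no
global RNG state leaks (`with_seed` restores the caller's stream).

What the generator does *not* emulate: human learning across games, the
slight acceleration seen between the first and last game of a session,
imperfect reveal fidelity (unless configured), bursty non-Poisson activity,
or any strategic timing. Tests passing on synthetic data therefore validate
the *pipeline* — estimators, fits, metrics — under a known generating
process, not claims about human behavior.

## Decision rules

`decision_rule()` builds the per-position update rules; all of them return a
probability distribution over the three colors given the player's current
color and the neighbor color counts $(n_R, n_B, n_Y)$:

* **majority** — the most frequent neighbor color, ties broken uniformly
  among the tied colors;
* **voter** — a color drawn from the neighborhood. "A color at random from
  the ones present in the neighborhood" is ambiguous between
  frequency-weighted and uniform-over-distinct-colors; the default
  (`voter_mode = "weighted"`) draws from the multiset, matching the
  canonical voter model, and `"distinct"` gives the other reading;
* **random** — uniform over the alphabet regardless of neighbors;
* **bayesian** — the posterior below;
* **empirical_table** — probabilities looked up from an estimated
  transition table (see below), conditioned on the current color by
  default; undefined (never-observed) cells fall back to the uniform
  distribution so simulations cannot stall.

With a silent neighborhood, voter and majority also fall back to uniform.

## The Bayesian aggregation model

Players are modeled as Bayesian agents. A neighbor currently showing color
$x$ is a signal about the position's true color; signals matching the truth
have likelihood $C_0$, mismatching ones $C'$, and only $s = C'/C_0$ matters.
After $n_R, n_B, n_Y$ signals the posterior weight of color $x$ is
proportional to $s^{-n_x}$. With a uniform prior
(`bayes_posterior_uniform()`):

$$P(X) = \frac{1}{1 + \sum_{x \ne X} s^{\,n_X - n_x}},$$

and with a prior that favors the agent's current color $A$ by the odds
$a = P_{pre}(\text{other})/P_{pre}(\text{current})$ (`bayes_posterior()`):

$$P(X \mid A = X) = \frac{1}{1 + a \sum_{x \ne X} s^{\,n_X - n_x}}, \qquad
  P(X \mid A \ne X) = \frac{1}{1 + a^{-1} s^{\,n_X - n_A} +
  \sum_{x \notin \{X, A\}} s^{\,n_X - n_x}}.$$

Both are implemented through the common weight form ($w_x = s^{-n_x}$,
with $w_A$ multiplied by $1/a$), which makes normalization exact by
construction and is verified to $10^{-12}$ across randomized sweeps.

Interpretation: $s = 1$ cancels social information, $s < 1$ means the
neighborhood outweighs one's own opinion; $a = 1$ makes the current state
irrelevant (with equal counts every color gets exactly $1/3$), $a < 1$ is
inertia, with the stay probability tending to 1 as $a \to 0$. Note that the
three-color normalization gives $1/3$ — not $1/2$ — for the fully
uninformative case; prose descriptions of this limit sometimes quote the
binary-choice value, but the equations, and this implementation, are
three-color.

```{r posterior}
bayes_posterior_uniform(c(R = 4, B = 0, Y = 0), s = 0.5)   # 8/9 for R
bayes_posterior(c(R = 1, B = 1, Y = 1), "R", s = 0.57, a = 0.19)
```

## Transition events and empirical probabilities

`extract_transitions()` turns a log into decision events: for each pair of
consecutive proposals by one player and each of her unknown positions, one
event records the prior color, the new color, and the counts of informative
neighbors per color. Neighbor state is read *strictly before* the deciding
proposal's time, so a simultaneous update cannot influence the decision
(causality); neighbors with no proposal yet are excluded, and the effective
neighborhood size `k_eff` is recorded. Events are pooled across positions
and players without weighting.

`transition_table()` estimates:

* $P(X \mid n_X)$ — the probability that a decision ends on color $X$
  (switching to it *or remaining on it*; a flag restricts to strict
  changes) given $n_X$ neighbors showing $X$;
* stay curves $P(X \mid X;\, n_X)$ and switch curves
  $P(X \mid \bar X;\, n_X)$, per color and pooled over colors;
* the empirical frequencies of full neighbor configurations per prior
  color, which the model fits need.

Cells with no events are `NA` (undefined, never 0); cells with fewer than
`min_count = 5` events are flagged and excluded from fitting (a variance
control; the threshold is configurable).

## Fitting by grid-search RMSE

The model predicts probabilities given the *full* configuration
$(n_R, n_B, n_Y)$, while the empirical curves are marginals over one count
axis. `predict_empirical_curves()` therefore averages the exact posterior
over the observed configurations mapping to each marginal cell, weighted by
their empirical frequencies. How to collapse the full-configuration
dependence onto the $n_X$ axis is a genuinely open choice; empirical
weighting is used because it makes the model prediction exactly comparable
to what the estimator computes on the same events.

`fit_one_param()` scans $s \in \{0.05, 0.06, \ldots, 2.00\}$ and reports the
RMSE between the empirical per-color $P(X \mid n_X)$ cells and the
uniform-prior model; `fit_two_param()` scans the same grid in $(s, a)$
against the color-pooled stay and switch curves. Squared errors are averaged
unweighted over eligible cells (a count-weighted variant is available); the
optimum is the grid minimum, with exact ties broken toward the smallest $s$
then smallest $a$. Self-fit on curves generated exactly from the model
returns zero RMSE at the generating grid point, and tables built from
$\ge 5 \times 10^4$ simulated Bayesian-rule events recover $(s, a)$ within
$\pm 0.05$.

## Descriptive metrics

* `accuracy_curve()` — $p(t) = \frac{1}{N}\sum_j \sum_i
  \delta_{x_j(l_i,t),\,c(i)}$ on a 1 s grid, closed at proposal instants.
  Players with no proposal yet contribute 0 correct positions (keeping $N$
  fixed, as the defining formula does); an `"exclude"` mode averages only
  over players that have proposed, since the original convention is not
  stated.
* `interproposal_fit()` — the exponential rate by closed-form MLE,
  $b = 1/\overline{\Delta t}$, never an iterative fit. A caveat found while
  validating the pipeline: intervals observed *within* a 225 s game are
  right-truncated, which biases the naive MLE upward by roughly 15% at
  these rates (0.042 recovered from data generated at 0.036). The rate
  recovery test therefore uses long-duration logs, where truncation is
  negligible; on real 225 s sessions the fitted rate should be read as the
  within-game interval statistic it is.
* `end_hamming()` — mean pairwise Hamming distance of final codes; players
  who never proposed are excluded from pairs.
* `source_distance()` / `correctness_by_distance()` — BFS hop distance to
  the nearest source per (player, position), and the fraction of correct
  cells by distance. The distance-1 vs distance-2 advantage ratio pools
  correct cell-seconds over the whole game before dividing, avoiding
  unstable early-game denominators. Under the uniform covering reveal
  draw, distances up to 4–5 occur on these geometries (most often on the
  ring); the package reports whatever the realized maximum is.
* `source_fidelity()` — fraction of revealed cells set to the true color
  over all proposals (per proposal-cell; a per-player-position reading of
  the same statistic would differ, and is not implemented), plus the count
  of revealed-position changes between consecutive proposals.
* `compare_topologies()` — at each grid second, the unpaired two-sided
  Mann–Whitney U test and the paired two-sided Wilcoxon signed-rank test
  between per-game $p(t)$ values (delegated to `stats::wilcox.test`,
  normal approximation). Degenerate steps (no evidence) report p = 1 and
  are flagged; the 225 per-second tests are reported raw, without
  multiple-testing correction, as the analysis convention is.
* `game_score()`, `activity_histogram()`, `adaptation_summary()` — the
  reward schedule, proposals per 5 s bin, and per-game mean inter-proposal
  times.

## Rule comparison

`run_comparison()` runs each rule under matched conditions — either fully
synthetic (fresh network, target and reveals per realization) or in replay
mode, which reuses a reference log's network, initial conditions and exact
proposal schedule and replaces only the decisions (the special rule
`"copy"` reproduces the reference verbatim, a harness self-test). Fifty
realizations per rule per topology is the default, matching the scale of
the original comparison. With no experimental table available in this
repository, the `empirical_table` entry is fed a table estimated from
Bayesian-rule play at the fitted $(0.57, 0.19)$ — the package's stand-in
for the experimentally determined probabilities.

Two analytic anchors make the comparison interpretable: the random rule's
end-of-game accuracy is $3 + 7/3 \approx 5.33$ in expectation (3 revealed
positions always correct, 7 independent uniform guesses), and the ordering
majority $\ge$ voter $\ge$ Bayesian/empirical $>$ random is stable across
both topologies.

## Problem sizes and numerical choices

The packaged tests and the acceptance script size their simulations as
follows: 40 games (20 players each) for parameter recovery, $4 \times 10^5$
directly sampled decision events for estimator coherence (chosen so that
binomial noise in the sparsest cells, about $1/35$ of events, stays well
below the 0.02 coherence bound), 50 realizations per rule and topology for
the comparison, and 100 randomized small logs for the I/O round-trip. Grids
are the defaults above; probabilities are compared at $10^{-12}$ where
exact and at binomial-error scale where estimated.

## Known limitations

* The archive adapter (`adapt_external_archive()`) maps externally
  deposited session archives only through an explicit user-supplied column
  mapping; without one it fails closed. Replication of the original
  sessions' headline numbers therefore requires obtaining that archive and
  writing its mapping.
* The simulator permits resubmitting an unchanged code; whether humans
  could is unknown, and the transition estimator treats such proposals as
  ordinary (stay) events.
* Fitting assumes the three-color alphabet; two-color games simulate but
  are not supported by the model-fitting layer.
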