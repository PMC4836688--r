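# Demo session: the first study session's human games (20 players, k = 4,
# topology order random, regular, regular, random), simulated with the
# Bayesian rule at the parameters fitted to the experiments.
n_players: 20
k: 4
topologies: [random_regular, regular_lattice, regular_lattice, random_regular]
L: 10
n_colors: 3
reveals_per_player: 3
duration_s: 225
proposal_rate_per_s: 0.036
fidelity: 1
seed: 20140507
rule:
  name: bayesian
  s: 0.57
  a: 0.19
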