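# In-code fixtures: tiny hand-built games and generators used across tests.

with_seed <- crowdguess:::with_seed

build_network <- function(n, edges, k, topology = "regular_lattice") {
  structure(
    list(n_nodes = as.integer(n), k = as.integer(k), topology = topology,
         edges = crowdguess:::canonical_edges(edges)),
    class = "guess_network"
  )
}

build_setup <- function(target, reveals, duration_s = 225,
                        proposal_rate_per_s = 0.036) {
  structure(
    list(target = target, reveals = reveals,
         n_players = length(reveals), L = length(target), n_colors = 3L,
         alphabet = code_alphabet(), reveals_per_player = length(reveals[[1]]),
         duration_s = duration_s, proposal_rate_per_s = proposal_rate_per_s),
    class = "guess_setup"
  )
}

build_log <- function(setup, network, events, game_id = "g01",
                      provenance = "synthetic:fixture") {
  structure(
    list(setup = setup, network = network, events = events,
         game_id = game_id, provenance = provenance),
    class = "guess_log"
  )
}

# Two connected players, L = 10, 3 reveals each; proposal history chosen so
# transition neighbor counts can be tallied by hand.
two_player_log <- function() {
  target <- string_to_code("RBYRRYBBYR")
  setup <- build_setup(target, list(c(1L, 2L, 3L), c(8L, 9L, 10L)))
  network <- build_network(2, cbind(1L, 2L), k = 1)
  events <- data.frame(
    player = c(2L, 1L, 1L, 2L, 1L),
    time_s = c(10, 20, 40, 50, 60),
    code = c("YYYYYYYBYR",   # p2 first
             "RBYBBBBYYY",   # p1 first
             "RBYYYYYBBB",   # p1 second
             "BBBBBBBBYR",   # p2 second
             "RBYRRYBBYR"),  # p1 third (the target)
    stringsAsFactors = FALSE
  )
  build_log(setup, network, events)
}

# A small, fast session configuration for I/O round trips.
tiny_config <- function(rule = decision_rule("random")) {
  session_config(n_players = 4, k = 2,
                 topologies = c("regular_lattice", "random_regular"),
                 rule = rule, L = 4, reveals_per_player = 2,
                 duration_s = 30, proposal_rate_per_s = 0.2)
}

tiny_log <- function(seed, topology = "regular_lattice",
                     rule = decision_rule("random"), game_id = "g01") {
  cfg <- tiny_config(rule)
  withr_seed <- seed  # explicit seed keeps the fixture reproducible
  net <- make_network(cfg$n_players, cfg$k, topology, seed = withr_seed)
  setup <- make_game_setup(cfg$n_players, L = cfg$L,
                           reveals_per_player = cfg$reveals_per_player,
                           duration_s = cfg$duration_s,
                           proposal_rate_per_s = cfg$proposal_rate_per_s,
                           seed = withr_seed + 1)
  simulate_game(setup, net, rule, seed = withr_seed + 2, game_id = game_id)
}

# Build a ZIP archive (stored entries) from a directory, using the Python
# interpreter shipped with the environment; R's utils::zip needs an external
# zip binary that is not present.
make_zip <- function(zipfile, dir) {
  script <- sprintf(
    "import os, sys, zipfile\nzf = zipfile.ZipFile(%s, 'w')\nfor root, _, files in os.walk(%s):\n    for f in sorted(files):\n        p = os.path.join(root, f)\n        zf.write(p, os.path.relpath(p, %s))\nzf.close()\n",
    deparse(zipfile), deparse(dir), deparse(dir))
  status <- system2("python", c("-c", shQuote(script)))
  stopifnot(status == 0, file.exists(zipfile))
  zipfile
}

# Build a transition table whose empirical curves equal the model's own
# predictions at given parameters (exact self-fit target).
model_exact_table <- function(s, a, seed = 1, n_events = 5000) {
  ev <- sample_rule_events(decision_rule("bayesian", s = s, a = a),
                           n_events, seed = seed)
  tab <- transition_table(ev)
  pred2 <- predict_empirical_curves(tab, s, a)
  tab$stay_agg$p <- pred2$p_model[pred2$curve == "stay_agg"]
  tab$switch_agg$p <- pred2$p_model[pred2$curve == "switch_agg"]
  pred1 <- predict_empirical_curves(tab, s)
  tab$to_color$p <- pred1$p_model
  tab$to_color$count <- pmax(tab$to_color$count, 1000L)
  tab$stay_agg$count <- pmax(tab$stay_agg$count, 1000L)
  tab$switch_agg$count <- pmax(tab$switch_agg$count, 1000L)
  tab
}

expect_prob_vector <- function(p, tol = 1e-12) {
  expect_true(all(p >= 0))
  expect_equal(sum(p), 1, tolerance = tol)
}
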