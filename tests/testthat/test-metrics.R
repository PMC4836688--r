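test_that("latest_code_at carries proposals forward with a closed boundary", {
  log <- two_player_log()
  expect_true(is.na(latest_code_at(log, 1, 10)))   # before first proposal
  expect_equal(latest_code_at(log, 1, 20), "RBYBBBBYYY")  # exactly at t
  expect_equal(latest_code_at(log, 1, 39.9), "RBYBBBBYYY")  # between proposals
  expect_equal(latest_code_at(log, 1, 225), "RBYRRYBBYR")
  expect_error(latest_code_at(log, 5, 10), "unknown player")
})

test_that("accuracy curve evaluates the defining per-player sum", {
  # 2 players; player 1 proposes at t = 30 with 4 correct positions
  target <- string_to_code("RRRRRRRRRR")
  setup <- build_setup(target, list(c(1L, 2L, 3L), c(8L, 9L, 10L)))
  net <- build_network(2, cbind(1L, 2L), k = 1)
  log <- build_log(setup, net, data.frame(
    player = 1L, time_s = 30, code = "RRRRBBBBBB", stringsAsFactors = FALSE
  ))
  cv <- accuracy_curve(log)
  expect_equal(cv$p[cv$time < 30], rep(0, 30))
  expect_equal(cv$p[cv$time >= 30], rep(2, 196))  # (4 + 0)/2
  cv2 <- accuracy_curve(log, absent = "exclude")
  expect_equal(cv2$p[cv2$time >= 30], rep(4, 196))
  # all players holding the target gives p(t) = L
  perfect <- build_log(setup, net, data.frame(
    player = c(1L, 2L), time_s = c(1, 2),
    code = rep("RRRRRRRRRR", 2), stringsAsFactors = FALSE
  ))
  expect_equal(accuracy_curve(perfect)$p[-(1:2)], rep(10, 224))
})

test_that("accuracy is invariant under player relabeling and color permutation", {
  log <- tiny_log(31, rule = decision_rule("voter"))
  base <- accuracy_curve(log)$p
  # relabel players by a permutation
  perm <- c(3L, 1L, 4L, 2L)
  relab <- log
  relab$events$player <- perm[log$events$player]
  relab$setup$reveals <- log$setup$reveals[order(perm)]
  expect_equal(accuracy_curve(relab)$p, base)
  # jointly permute colors in target and proposals
  swap <- function(s) chartr("RBY", "YRB", s)
  recol <- log
  recol$setup$target <- strsplit(swap(code_to_string(log$setup$target)), "")[[1]]
  recol$events$code <- swap(log$events$code)
  expect_equal(accuracy_curve(recol)$p, base)
})

test_that("exponential fit is the closed-form MLE", {
  setup <- build_setup(string_to_code("RRRRRRRRRR"),
                       list(c(1L, 2L, 3L), c(8L, 9L, 10L)))
  net <- build_network(2, cbind(1L, 2L), k = 1)
  log <- build_log(setup, net, data.frame(
    player = 1L, time_s = c(10, 35, 60, 85),
    code = rep("RRRRRRRRRR", 4), stringsAsFactors = FALSE
  ))
  fit <- interproposal_fit(log)
  expect_equal(fit$rate, 0.04)          # all intervals exactly 25 s
  expect_equal(fit$characteristic_time, 25)
  expect_equal(fit$n, 3)
  iv <- c(3.2, 8.9, 1.1, 44)
  log2 <- build_log(setup, net, data.frame(
    player = 1L, time_s = cumsum(c(1, iv)),
    code = rep("RRRRRRRRRR", 5), stringsAsFactors = FALSE
  ))
  expect_equal(interproposal_fit(log2)$rate, 1 / mean(iv))
  empty <- build_log(setup, net, data.frame(
    player = integer(0), time_s = numeric(0), code = character(0)
  ))
  expect_error(interproposal_fit(empty), "no inter-proposal intervals")
})

test_that("activity histogram counts proposals per bin", {
  empty <- build_log(
    build_setup(string_to_code("RRRRRRRRRR"), list(c(1L, 2L, 3L), c(8L, 9L, 10L))),
    build_network(2, cbind(1L, 2L), k = 1),
    data.frame(player = integer(0), time_s = numeric(0), code = character(0))
  )
  h <- activity_histogram(empty)
  expect_true(all(h$count == 0))
  expect_equal(nrow(h), 45)
  # Poisson superposition: N * rate * bin proposals per bin in steady state
  log <- simulate_game(make_game_setup(20, duration_s = 2000, seed = 14),
                       make_network(20, 4, "regular_lattice"),
                       decision_rule("random"), seed = 15)
  h2 <- activity_histogram(log)
  steady <- h2$count[h2$bin_start >= 200]
  expect_equal(mean(steady), 20 * 0.036 * 5, tolerance = 0.1)
})

test_that("end-of-game Hamming distance averages over player pairs", {
  setup <- build_setup(string_to_code("RRRRRRRRRR"),
                       list(c(1L, 2L, 3L), c(8L, 9L, 10L)))
  net <- build_network(2, cbind(1L, 2L), k = 1)
  same <- build_log(setup, net, data.frame(
    player = c(1L, 2L), time_s = c(1, 2), code = rep("RBYRBYRBYR", 2)
  ))
  expect_equal(end_hamming(same), 0)
  diff3 <- build_log(setup, net, data.frame(
    player = c(1L, 2L), time_s = c(1, 2), code = c("RRRRRRRRRR", "RRRRRRRBBB")
  ))
  expect_equal(end_hamming(diff3), 3)
  solo <- build_log(setup, net, data.frame(
    player = 1L, time_s = 1, code = "RRRRRRRRRR"
  ))
  expect_error(end_hamming(solo), ">= 2 players")
})

test_that("source distances are BFS distances to the nearest source", {
  # 6-node ring (k = 2); position 1 revealed only to node 1
  net <- make_network(6, 2, "regular_lattice")
  reveals <- c(list(1L), rep(list(2L), 5))
  d <- source_distance(net, reveals, 1)
  # brute-force all-pairs shortest paths on the toy ring
  expected <- c(0L, 1L, 2L, 3L, 2L, 1L)
  expect_equal(d, expected)
  expect_equal(d[1], 0L)  # a source has distance 0
  expect_error(source_distance(net, reveals, 3), "no source")
})

test_that("correctness by distance tracks propagation from sources", {
  # every player holds the target: fractions 1 at every distance, ratio 1
  net <- make_network(6, 2, "regular_lattice")
  target <- string_to_code("RRRRRRRRRR")
  reveals <- lapply(1:6, function(j) ((2 * (j - 1) + 0:1) %% 10) + 1L)
  setup <- build_setup(target, reveals)
  log <- build_log(setup, net, data.frame(
    player = 1:6, time_s = 1:6 / 10, code = rep("RRRRRRRRRR", 6)
  ))
  rep <- correctness_by_distance(log)
  expect_true(all(abs(rep$aggregate$fraction - 1) < 0.01))
  expect_equal(rep$ratio, 1, tolerance = 0.01)
  # propagation: closer to the source means more often correct (voter games)
  logs <- with_seed(61, lapply(1:50, function(i) {
    simulate_game(make_game_setup(20), make_network(20, 4, "random_regular"),
                  decision_rule("voter"))
  }))
  rep2 <- correctness_by_distance(logs)
  expect_gt(rep2$ratio, 1)
})

test_that("source fidelity counts revealed-cell accuracy and changes", {
  log <- simulate_game(make_game_setup(10, seed = 16),
                       make_network(10, 4, "regular_lattice"),
                       decision_rule("voter"), seed = 17)
  fid <- source_fidelity(log)
  expect_equal(fid$fraction_correct, 1)
  expect_equal(fid$n_changes, 0)
  # hand-built: player 1 (reveals 1..3) flips position 2 once in 3 proposals
  setup <- build_setup(string_to_code("RRRRRRRRRR"),
                       list(c(1L, 2L, 3L), c(8L, 9L, 10L)))
  net <- build_network(2, cbind(1L, 2L), k = 1)
  log2 <- build_log(setup, net, data.frame(
    player = 1L, time_s = c(1, 2, 3),
    code = c("RRRRRRRRRR", "RBRRRRRRRR", "RBRRRRRRRR")
  ))
  fid2 <- source_fidelity(log2)
  expect_equal(fid2$n_changes, 1)
  expect_equal(fid2$n_proposals, 3)
  expect_equal(fid2$fraction_correct, 7 / 9)  # flip persists in proposal 3
})

test_that("game scores follow the reward schedule", {
  target <- string_to_code("RBYRRYBBYR")
  expect_equal(game_score("RBYRRYBBYR", target, finished = TRUE), 2010)
  expect_equal(game_score("YYRYYRYYRY", target, finished = TRUE), 10)
  expect_equal(game_score("RBYRRYBYRB", target, finished = TRUE), 710)
  expect_equal(game_score("RBYRRYBBYR", target, finished = FALSE), 2000)
})

test_that("topology comparison runs both rank tests per second", {
  # degenerate: identical paired curves carry no evidence
  log <- tiny_log(71)
  cv <- accuracy_curve(log)
  cmp <- compare_topologies(list(cv, cv), list(cv, cv))
  expect_true(all(cmp$table$p_paired == 1))
  expect_true(all(cmp$table$degenerate))
  # null sanity: same-distribution curves should not look different
  mk <- function(seeds) lapply(seeds, function(s) {
    accuracy_curve(simulate_game(
      make_game_setup(10, seed = s), make_network(10, 4, "random_regular", seed = s),
      decision_rule("majority"), seed = s + 1000
    ))
  })
  cmp2 <- compare_topologies(mk(1:5), mk(101:105))
  expect_gt(cmp2$mean_p_unpaired, 0.1)
  expect_error(compare_topologies(list(cv), list(cv)), ">= 2 games")
})

test_that("adaptation summary orders per-game mean inter-proposal times", {
  cfg_slow <- session_config(n_players = 10, topologies = "regular_lattice",
                             rule = decision_rule("random"),
                             proposal_rate_per_s = 0.03)
  cfg_fast <- session_config(n_players = 10, topologies = "regular_lattice",
                             rule = decision_rule("random"),
                             proposal_rate_per_s = 0.05)
  logs <- c(simulate_session(cfg_slow, seed = 22),
            simulate_session(cfg_fast, seed = 23))
  adapt <- adaptation_summary(logs)
  expect_equal(nrow(adapt), 2)
  expect_gt(adapt$mean_interproposal_s[1], adapt$mean_interproposal_s[2])
  expect_error(adaptation_summary(logs[1]), ">= 2 games")
})
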