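test_that("simulated games are deterministic given a seed and structurally valid", {
  setup <- make_game_setup(20, seed = 3)
  net <- make_network(20, 4, "random_regular", seed = 4)
  rule <- decision_rule("majority")
  a <- simulate_game(setup, net, rule, seed = 10)
  b <- simulate_game(setup, net, rule, seed = 10)
  expect_identical(a$events, b$events)
  ev <- a$events
  expect_false(is.unsorted(ev$time_s))
  expect_true(all(ev$time_s >= 0 & ev$time_s <= 225))
  for (j in unique(ev$player)) {
    expect_true(all(diff(ev$time_s[ev$player == j]) > 0))
  }
  expect_error(simulate_game(make_game_setup(17, seed = 1), net, rule),
               "17 players")
})

test_that("revealed positions always show the target at fidelity 1", {
  log <- simulate_game(make_game_setup(20, seed = 5),
                       make_network(20, 4, "regular_lattice"),
                       decision_rule("voter"), seed = 6)
  for (r in seq_len(nrow(log$events))) {
    j <- log$events$player[r]
    code <- strsplit(log$events$code[r], "")[[1]]
    rv <- log$setup$reveals[[j]]
    expect_identical(code[rv], log$setup$target[rv])
  }
})

test_that("fidelity below 1 lets revealed positions drift occasionally", {
  log <- simulate_game(make_game_setup(20, seed = 5),
                       make_network(20, 4, "regular_lattice"),
                       decision_rule("random"), seed = 6, fidelity = 0.8)
  fid <- source_fidelity(log)
  expect_lt(fid$fraction_correct, 1)
  expect_gt(fid$fraction_correct, 0.6)
  expect_gt(fid$n_changes, 0)
})

test_that("random-rule games reach the analytic accuracy asymptote", {
  # revealed positions are always correct and each of the other 7 positions
  # is right with probability 1/3: expect 3 + 7/3 correct at game end
  ends <- with_seed(2024, {
    vapply(1:200, function(i) {
      setup <- make_game_setup(20)
      net <- make_network(20, 4, "regular_lattice")
      log <- simulate_game(setup, net, decision_rule("random"))
      cv <- accuracy_curve(log)
      cv$p[length(cv$p)]
    }, numeric(1))
  })
  expect_equal(mean(ends), 3 + 7 / 3, tolerance = 0.02)  # MC se ~ 0.02/5.33
})

test_that("inter-proposal times are exponential at the configured rate", {
  setup <- make_game_setup(20, duration_s = 15000, seed = 8)
  net <- make_network(20, 4, "regular_lattice")
  log <- simulate_game(setup, net, decision_rule("random"), seed = 9)
  fit <- interproposal_fit(log)
  expect_gt(fit$n, 10000)
  expect_equal(fit$rate, 0.036, tolerance = 0.05)
})

test_that("sessions follow the configured topology order and player count", {
  logs1 <- simulate_session(experiment_session_config(1), seed = 11)
  expect_length(logs1, 4)
  expect_equal(vapply(logs1, function(l) l$network$topology, character(1)),
               c("random_regular", "regular_lattice", "regular_lattice",
                 "random_regular"))
  logs2 <- simulate_session(experiment_session_config(2), seed = 12)
  expect_true(all(vapply(logs2, function(l) l$setup$n_players, integer(1)) == 17L))
  again <- simulate_session(experiment_session_config(2), seed = 12)
  expect_identical(lapply(logs2, `[[`, "events"), lapply(again, `[[`, "events"))
})

test_that("replaying with the copy rule reproduces the reference exactly", {
  ref <- tiny_log(21, rule = decision_rule("majority"))
  copy <- replay_game(ref, "copy")
  expect_identical(copy$events, ref$events)
  expect_identical(accuracy_curve(copy)$p, accuracy_curve(ref)$p)
  # replaying with another rule keeps the schedule but redraws decisions
  redrawn <- replay_game(ref, decision_rule("random"), seed = 1)
  expect_identical(redrawn$events[c("player", "time_s")],
                   ref$events[c("player", "time_s")])
})

test_that("sampled rule events carry uniform full-neighborhood configurations", {
  ev <- sample_rule_events(decision_rule("random"), 2000, seed = 13)
  expect_equal(nrow(ev), 2000)
  expect_true(all(ev$n_R + ev$n_B + ev$n_Y == 4))
  expect_true(all(ev$k_eff == 4))
  again <- sample_rule_events(decision_rule("random"), 2000, seed = 13)
  expect_identical(ev, again)
})
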