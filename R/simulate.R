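#' Simulate one guessing game
#'
#' Event-driven agent-based simulation mimicking the experimental protocol.
#' Each player proposes complete codes at exponential inter-proposal times
#' (rate `proposal_rate_per_s`); proposals after `duration_s` are discarded.
#' The first proposal fills revealed positions with their true colors and the
#' remaining positions by the rule applied with no neighbor information
#' (which reduces to a uniform draw). Every later proposal keeps revealed
#' positions at the true color (with probability `fidelity`; the experiments
#' show near-perfect fidelity) and redraws each unknown position
#' independently with [decide_position()], using the latest codes submitted
#' by neighbors at that instant. Neighbors that have not proposed yet are
#' excluded from the neighbor counts.
#'
#' @param setup A [make_game_setup()] object.
#' @param network A [make_network()] object with `n_nodes == n_players`.
#' @param rule A [decision_rule()].
#' @param seed Optional integer seed; the whole game is deterministic given
#'   the seed.
#' @param fidelity Probability that each revealed position is set to its true
#'   color (default 1; with probability `1 - fidelity` a wrong color is drawn
#'   uniformly).
#' @param game_id Identifier used in file names and reports.
#' @return An object of class `guess_log`: list with `setup`, `network`,
#'   `events` (data frame `player`, `time_s`, `code`, time-ordered, codes as
#'   `L`-character strings), `game_id` and `provenance`.
#' @export
simulate_game <- function(setup, network, rule, seed = NULL, fidelity = 1,
                          game_id = "game01") {
  stopifnot(inherits(setup, "guess_setup"), inherits(network, "guess_network"),
            inherits(rule, "decision_rule"))
  if (setup$n_players != network$n_nodes) {
    stop_("setup has ", setup$n_players, " players but network has ",
          network$n_nodes, " nodes")
  }
  if (fidelity < 0 || fidelity > 1) stop_("fidelity must be in [0, 1]")
  with_seed(seed, {
    sched <- draw_schedule(setup$n_players, setup$proposal_rate_per_s,
                           setup$duration_s)
    events <- run_schedule(sched, setup, network, rule, fidelity)
    structure(
      list(setup = setup, network = network, events = events,
           game_id = game_id,
           provenance = paste0("synthetic:", rule$name)),
      class = "guess_log"
    )
  })
}

# Exponential proposal times per player, truncated at the game duration.
# Ties across players are broken by drawing order; zero inter-proposal
# intervals (possible only in principle) are resampled to keep per-player
# times strictly increasing.
draw_schedule <- function(n_players, rate, duration) {
  player <- integer(0); time_s <- numeric(0)
  for (j in seq_len(n_players)) {
    t <- 0
    repeat {
      dt <- stats::rexp(1, rate)
      while (dt == 0) dt <- stats::rexp(1, rate)
      t <- t + dt
      if (t > duration) break
      player <- c(player, j); time_s <- c(time_s, t)
    }
  }
  ord <- order(time_s, seq_along(time_s))
  data.frame(player = player[ord], time_s = time_s[ord])
}

run_schedule <- function(sched, setup, network, rule, fidelity,
                         copy_codes = NULL) {
  n <- setup$n_players; L <- setup$L
  alphabet <- setup$alphabet
  adj <- neighbors_of(network)
  state <- matrix(NA_character_, nrow = n, ncol = L)
  codes <- character(nrow(sched))
  for (e in seq_len(nrow(sched))) {
    j <- sched$player[e]
    if (!is.null(copy_codes)) {
      new <- strsplit(copy_codes[e], "")[[1]]
    } else {
      new <- propose_code(j, state, setup, adj, rule, fidelity, alphabet)
    }
    state[j, ] <- new
    codes[e] <- paste(new, collapse = "")
  }
  data.frame(player = sched$player, time_s = sched$time_s, code = codes)
}

propose_code <- function(j, state, setup, adj, rule, fidelity, alphabet) {
  L <- setup$L
  rv <- setup$reveals[[j]]
  new <- character(L)
  new[rv] <- setup$target[rv]
  if (fidelity < 1) {
    flip <- rv[stats::runif(length(rv)) > fidelity]
    for (i in flip) new[i] <- sample(setdiff(alphabet, setup$target[i]), 1)
  }
  first <- all(is.na(state[j, ]))
  unknown <- setdiff(seq_len(L), rv)
  for (i in unknown) {
    if (first) {
      # no neighbor information enters the first guess
      new[i] <- decide_position(rule, NA, character(0), alphabet)
    } else {
      nb <- state[adj[[j]], i]
      new[i] <- decide_position(rule, state[j, i], nb[!is.na(nb)], alphabet)
    }
  }
  new
}

#' Replay a reference game under a different decision rule
#'
#' Reuses the reference log's network, target, reveal assignment and exact
#' proposal schedule (the "same temporal sequence of updates"), replacing
#' only the color decisions by draws from `rule`. The special rule name
#' `"copy"` reproduces the reference decisions verbatim.
#'
#' @param ref A `guess_log` to replay.
#' @param rule A [decision_rule()], or the string `"copy"`.
#' @param seed Optional integer seed.
#' @param fidelity Revealed-position fidelity for the replayed decisions.
#' @return A new `guess_log` with the same schedule.
#' @export
replay_game <- function(ref, rule, seed = NULL, fidelity = 1) {
  stopifnot(inherits(ref, "guess_log"))
  sched <- ref$events[c("player", "time_s")]
  with_seed(seed, {
    if (identical(rule, "copy")) {
      events <- run_schedule(sched, ref$setup, ref$network, NULL, fidelity,
                             copy_codes = ref$events$code)
      prov <- "replay:copy"
    } else {
      stopifnot(inherits(rule, "decision_rule"))
      events <- run_schedule(sched, ref$setup, ref$network, rule, fidelity)
      prov <- paste0("replay:", rule$name)
    }
    structure(
      list(setup = ref$setup, network = ref$network, events = events,
           game_id = ref$game_id, provenance = prov),
      class = "guess_log"
    )
  })
}

#' Simulate a full session of games
#'
#' One game per entry of `config$topologies`, each with a fresh network,
#' target and reveal assignment, in the configured topology order.
#'
#' @param config A [session_config()].
#' @param seed Optional integer seed for the whole session.
#' @return List of `guess_log`, one per game.
#' @export
simulate_session <- function(config, seed = NULL) {
  stopifnot(inherits(config, "session_config"))
  with_seed(seed, {
    lapply(seq_along(config$topologies), function(g) {
      net <- make_network(config$n_players, config$k, config$topologies[g])
      setup <- make_game_setup(
        config$n_players, L = config$L, n_colors = config$n_colors,
        reveals_per_player = config$reveals_per_player,
        duration_s = config$duration_s,
        proposal_rate_per_s = config$proposal_rate_per_s
      )
      simulate_game(setup, net, config$rules[[g]], fidelity = config$fidelity,
                    game_id = sprintf("game%02d", g))
    })
  })
}

#' @export
print.guess_log <- function(x, ...) {
  cat(sprintf("<guess_log> %s [%s]: %d players on %s, %d proposals in %gs\n",
              x$game_id, x$provenance, x$setup$n_players,
              x$network$topology, nrow(x$events), x$setup$duration_s))
  invisible(x)
}

#' Sample bare transition events under a known rule
#'
#' Draws decision events directly (without running full games): the prior
#' color is uniform, the neighbor configuration `(n_R, n_B, n_Y)` is uniform
#' over all compositions summing to `k`, and the final color is sampled from
#' the rule's distribution. Used to test and calibrate the transition-table
#' estimator against a known generating process.
#'
#' @param rule A [decision_rule()].
#' @param n_events Number of events.
#' @param k Neighborhood size.
#' @param alphabet Color alphabet.
#' @param seed Optional integer seed.
#' @return Data frame with columns `from`, `to`, `n_R`, `n_B`, `n_Y`,
#'   `k_eff` — the event schema of [extract_transitions()].
#' @export
sample_rule_events <- function(rule, n_events, k = 4,
                               alphabet = code_alphabet(), seed = NULL) {
  stopifnot(inherits(rule, "decision_rule"))
  configs <- compositions_of(k, length(alphabet))
  with_seed(seed, {
    ci <- sample.int(nrow(configs), n_events, replace = TRUE)
    from <- sample(alphabet, n_events, replace = TRUE)
    to <- character(n_events)
    key <- paste(from, ci)
    for (u in unique(key)) {
      idx <- which(key == u)
      counts <- stats::setNames(configs[ci[idx[1]], ], alphabet)
      p <- rule_distribution(rule, from[idx[1]], counts)
      to[idx] <- alphabet[sample.int(length(alphabet), length(idx),
                                     replace = TRUE, prob = p)]
    }
    out <- data.frame(from = from, to = to)
    for (m in seq_along(alphabet)) out[[paste0("n_", alphabet[m])]] <- configs[ci, m]
    out$k_eff <- k
    out
  })
}

compositions_of <- function(k, m) {
  if (m == 2) {
    cbind(0:k, k:0)
  } else {
    do.call(rbind, lapply(0:k, function(a) {
      cbind(a, compositions_of(k - a, m - 1))
    }))
  }
}
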