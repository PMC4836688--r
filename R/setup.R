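#' Draw a game setup: target code and revealed positions
#'
#' At the start of a game every player privately sees `reveals_per_player`
#' positions of the common target code (the study showed 3 of 10). Reveal
#' sets are drawn uniformly at random subject to the constraint that their
#' union covers the full code, matching the experimental randomization.
#'
#' @param n_players Number of players.
#' @param L Code length (default 10).
#' @param n_colors Number of colors (default 3).
#' @param reveals_per_player Revealed positions per player (default 3).
#' @param duration_s Game duration in seconds (default 225).
#' @param proposal_rate_per_s Per-player proposal rate in 1/s (default 0.036,
#'   the rate of the exponential inter-proposal fit to the experiments).
#' @param seed Optional integer seed.
#' @param max_tries Rejection-sampling cap for the coverage constraint.
#' @return An object of class `guess_setup` with fields `target` (character
#'   vector of length `L`), `reveals` (list of integer position vectors, one
#'   per player), `alphabet`, and the scalar parameters above.
#' @export
make_game_setup <- function(n_players, L = 10, n_colors = 3,
                            reveals_per_player = 3, duration_s = 225,
                            proposal_rate_per_s = 0.036, seed = NULL,
                            max_tries = 10000) {
  if (!is_count(n_players) || !is_count(L) || !is_count(reveals_per_player)) {
    stop_("n_players, L and reveals_per_player must be positive integers")
  }
  if (reveals_per_player > L) stop_("reveals_per_player exceeds code length")
  if (n_players * reveals_per_player < L) {
    stop_("coverage infeasible: ", n_players, " players x ", reveals_per_player,
          " reveals = ", n_players * reveals_per_player, " < L = ", L)
  }
  if (!is.numeric(duration_s) || duration_s <= 0) stop_("duration_s must be > 0")
  if (!is.numeric(proposal_rate_per_s) || proposal_rate_per_s <= 0) {
    stop_("proposal_rate_per_s must be > 0")
  }
  alphabet <- code_alphabet(n_colors)
  with_seed(seed, {
    target <- sample(alphabet, L, replace = TRUE)
    reveals <- NULL
    for (i in seq_len(max_tries)) {
      cand <- lapply(seq_len(n_players), function(j) sort(sample.int(L, reveals_per_player)))
      if (length(unique(unlist(cand))) == L) {
        reveals <- cand
        break
      }
    }
    if (is.null(reveals)) stop_("failed to draw covering reveal sets in ", max_tries, " tries")
    structure(
      list(target = target, reveals = reveals,
           n_players = as.integer(n_players), L = as.integer(L),
           n_colors = as.integer(n_colors), alphabet = alphabet,
           reveals_per_player = as.integer(reveals_per_player),
           duration_s = as.numeric(duration_s),
           proposal_rate_per_s = as.numeric(proposal_rate_per_s)),
      class = "guess_setup"
    )
  })
}

#' @export
print.guess_setup <- function(x, ...) {
  cat(sprintf("<guess_setup> %d players, code %s, %d reveals each, %gs at %g/s\n",
              x$n_players, code_to_string(x$target), x$reveals_per_player,
              x$duration_s, x$proposal_rate_per_s))
  invisible(x)
}

#' Describe a session of games
#'
#' A session is an ordered series of games played by the same group on
#' (possibly) different network topologies. The two study sessions used four
#' human games each: topology order random, regular, regular, random with 20
#' players (session 1) and regular, random, random, regular with 17 players
#' (session 2).
#'
#' @param n_players Players per game.
#' @param k Node degree.
#' @param topologies Character vector giving the per-game topology order
#'   (values `"regular_lattice"` / `"random_regular"`).
#' @param rule A [decision_rule()] (or list of rules, one per game) driving
#'   the simulated players.
#' @param fidelity Probability that a revealed position is set to its true
#'   color in each proposal (the experiments show near-perfect fidelity).
#' @inheritParams make_game_setup
#' @return An object of class `session_config`.
#' @export
session_config <- function(n_players = 20, k = 4,
                           topologies = c("random_regular", "regular_lattice",
                                          "regular_lattice", "random_regular"),
                           rule = decision_rule("bayesian", s = 0.57, a = 0.19),
                           L = 10, n_colors = 3, reveals_per_player = 3,
                           duration_s = 225, proposal_rate_per_s = 0.036,
                           fidelity = 1) {
  bad <- setdiff(topologies, c("regular_lattice", "random_regular"))
  if (length(bad)) stop_("unknown topology name(s): ", paste(bad, collapse = ", "))
  rules <- if (inherits(rule, "decision_rule")) rep(list(rule), length(topologies)) else rule
  if (length(rules) != length(topologies)) {
    stop_("rule must be a single decision_rule or one per game")
  }
  stopifnot(all(vapply(rules, inherits, TRUE, "decision_rule")))
  structure(
    list(n_players = as.integer(n_players), k = as.integer(k),
         topologies = topologies, rules = rules, L = as.integer(L),
         n_colors = as.integer(n_colors),
         reveals_per_player = as.integer(reveals_per_player),
         duration_s = as.numeric(duration_s),
         proposal_rate_per_s = as.numeric(proposal_rate_per_s),
         fidelity = as.numeric(fidelity)),
    class = "session_config"
  )
}

#' Session configuration matching one of the two study sessions
#'
#' @param experiment 1 (20 players; topology order random, regular, regular,
#'   random) or 2 (17 players; regular, random, random, regular).
#' @param rule Decision rule for the simulated players.
#' @return A `session_config`.
#' @export
experiment_session_config <- function(experiment = 1,
                                      rule = decision_rule("bayesian", s = 0.57, a = 0.19)) {
  if (experiment == 1) {
    session_config(n_players = 20,
                   topologies = c("random_regular", "regular_lattice",
                                  "regular_lattice", "random_regular"),
                   rule = rule)
  } else if (experiment == 2) {
    session_config(n_players = 17,
                   topologies = c("regular_lattice", "random_regular",
                                  "random_regular", "regular_lattice"),
                   rule = rule)
  } else {
    stop_("experiment must be 1 or 2")
  }
}

#' Read a session configuration from a YAML file
#'
#' Recognized keys: `n_players`, `k`, `topologies`, `L`, `n_colors`,
#' `reveals_per_player`, `duration_s`, `proposal_rate_per_s`, `fidelity`,
#' `seed`, and `rule` (a map with `name` and, as needed, `s`, `a`,
#' `voter_mode`). Unknown keys are an error.
#'
#' @param path Path to a YAML file.
#' @return A `session_config`; any `seed` key is attached as attribute "seed".
#' @export
read_session_config <- function(path) {
  if (!file.exists(path)) stop_("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  known <- c("n_players", "k", "topologies", "L", "n_colors",
             "reveals_per_player", "duration_s", "proposal_rate_per_s",
             "fidelity", "seed", "rule")
  bad <- setdiff(names(raw), known)
  if (length(bad)) stop_("invalid config key(s): ", paste(bad, collapse = ", "))
  rule <- if (is.null(raw$rule)) {
    decision_rule("bayesian", s = 0.57, a = 0.19)
  } else {
    rule_from_list(raw$rule)
  }
  args <- raw[setdiff(names(raw), c("seed", "rule"))]
  args$rule <- rule
  cfg <- do.call(session_config, args)
  attr(cfg, "seed") <- raw$seed
  cfg
}

rule_from_list <- function(x) {
  if (is.null(x$name)) stop_("rule config needs a 'name' field")
  decision_rule(x$name, s = x$s, a = x$a,
                voter_mode = x$voter_mode %||% "weighted")
}
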