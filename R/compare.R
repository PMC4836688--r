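#' Compare decision rules under matched conditions
#'
#' Runs every rule under the same experimental conditions and aggregates
#' accuracy trajectories per topology. Two modes:
#'
#' * synthetic — `conditions` is a [session_config()]; each realization
#'   draws a fresh network, target and reveal assignment per topology and
#'   simulates the game with the rule's decisions.
#' * replay — `conditions` is a list of reference `guess_log`s; each
#'   realization reuses a reference log's network, initial conditions and
#'   exact proposal schedule (the "same temporal sequence of updates"),
#'   replacing only the decisions. Reference logs are cycled per topology.
#'
#' @param conditions A `session_config` or a list of `guess_log`.
#' @param rules Named list of [decision_rule()] objects (names label the
#'   report; unnamed lists are named by rule name).
#' @param n_realizations Simulated games per rule per topology (the study's
#'   comparison uses 50).
#' @param seed Optional integer seed for the whole comparison.
#' @param absent Passed to [accuracy_curve()].
#' @return Object of class `comparison_report`: list with `curves`
#'   (`curves[[topology]][[rule]]` = mean `p(t)` data frame), `end` (data
#'   frame `topology`, `rule`, `mean_end`, `se_end`, `n`), `n_realizations`,
#'   `mode`.
#' @export
run_comparison <- function(conditions, rules, n_realizations = 50,
                           seed = NULL, absent = "zero") {
  if (!length(rules)) stop_("empty rule list")
  if (is.null(names(rules)) || any(names(rules) == "")) {
    names(rules) <- vapply(rules, function(r) r$name, character(1))
  }
  stopifnot(all(vapply(rules, inherits, TRUE, "decision_rule")))
  replay <- !inherits(conditions, "session_config")
  if (replay) {
    conditions <- as_log_list(conditions)
    stopifnot(all(vapply(conditions, inherits, TRUE, "guess_log")))
    topologies <- unique(vapply(conditions, function(l) l$network$topology,
                                character(1)))
  } else {
    topologies <- unique(conditions$topologies)
  }
  with_seed(seed, {
    curves <- list(); end_rows <- list()
    for (topo in topologies) {
      curves[[topo]] <- list()
      refs <- if (replay) {
        Filter(function(l) l$network$topology == topo, conditions)
      }
      for (rn in names(rules)) {
        rule <- rules[[rn]]
        ends <- numeric(n_realizations)
        sum_p <- NULL
        for (r in seq_len(n_realizations)) {
          log <- if (replay) {
            replay_game(refs[[(r - 1) %% length(refs) + 1]], rule)
          } else {
            setup <- make_game_setup(
              conditions$n_players, L = conditions$L,
              n_colors = conditions$n_colors,
              reveals_per_player = conditions$reveals_per_player,
              duration_s = conditions$duration_s,
              proposal_rate_per_s = conditions$proposal_rate_per_s
            )
            net <- make_network(conditions$n_players, conditions$k, topo)
            simulate_game(setup, net, rule, fidelity = conditions$fidelity)
          }
          cv <- accuracy_curve(log, absent = absent)
          sum_p <- if (is.null(sum_p)) cv$p else sum_p + cv$p
          ends[r] <- cv$p[length(cv$p)]
        }
        curves[[topo]][[rn]] <- data.frame(
          time = seq_along(sum_p) - 1, p = sum_p / n_realizations
        )
        end_rows[[paste(topo, rn)]] <- data.frame(
          topology = topo, rule = rn, mean_end = mean(ends),
          se_end = stats::sd(ends) / sqrt(n_realizations), n = n_realizations
        )
      }
    }
    end <- do.call(rbind, end_rows)
    rownames(end) <- NULL
    structure(
      list(curves = curves, end = end, n_realizations = n_realizations,
           mode = if (replay) "replay" else "synthetic"),
      class = "comparison_report"
    )
  })
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf("<comparison_report> %s mode, %d realizations per rule/topology\n",
              x$mode, x$n_realizations))
  print(x$end)
  invisible(x)
}

#' Rank rules by end-of-game accuracy per topology
#'
#' @param report A [run_comparison()] report with at least two rules.
#' @return Data frame sorted by topology then descending mean end-of-game
#'   accuracy, with Monte-Carlo standard errors.
#' @export
rank_rules <- function(report) {
  stopifnot(inherits(report, "comparison_report"))
  if (length(unique(report$end$rule)) < 2) stop_("need >= 2 rules to rank")
  out <- report$end[order(report$end$topology, -report$end$mean_end), ]
  out$rank <- stats::ave(-out$mean_end, out$topology, FUN = rank)
  rownames(out) <- NULL
  out
}

#' Plot mean accuracy curves of a comparison report
#'
#' Diagnostic overlay of the per-rule mean `p(t)` curves, one panel per
#' topology. Requires `ggplot2`.
#'
#' @param report A `comparison_report`.
#' @return A ggplot object.
#' @export
plot_comparison <- function(report) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop_("plot_comparison requires the ggplot2 package")
  }
  df <- do.call(rbind, lapply(names(report$curves), function(topo) {
    do.call(rbind, lapply(names(report$curves[[topo]]), function(rn) {
      cbind(report$curves[[topo]][[rn]], topology = topo, rule = rn)
    }))
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = time, y = p, colour = rule)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~topology) +
    ggplot2::labs(x = "time (s)", y = "mean correct positions p(t)")
}
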