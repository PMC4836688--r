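# End-to-end pipeline commands. Each command writes its outputs plus a
# manifest.json capturing the configuration snapshot, seed, package
# version, input digests and output digests, so that deterministic stages
# can be re-run bit-identically.

write_manifest <- function(out_dir, config, seed, inputs = character(0)) {
  outputs <- setdiff(list.files(out_dir, recursive = TRUE), "manifest.json")
  manifest <- list(
    package = "crowdguess",
    version = as.character(utils::packageVersion("crowdguess")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    config = config,
    input_digests = as.list(tools::md5sum(inputs)),
    output_digests = as.list(tools::md5sum(file.path(out_dir, outputs)))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  invisible(manifest)
}

config_snapshot <- function(config) {
  if (inherits(config, "session_config")) {
    cfg <- unclass(config)
    cfg$rules <- lapply(cfg$rules, function(r) {
      c(list(name = r$name),
        if (r$name == "bayesian") list(s = r$params$s, a = r$params$a),
        if (r$name == "voter") list(voter_mode = r$params$voter_mode))
    })
    cfg
  } else {
    config
  }
}

ensure_dir <- function(path) {
  if (!dir.exists(path)) dir.create(path, recursive = TRUE)
  path
}

#' Simulate a session and write its log bundles
#'
#' @param config A [session_config()], or the path of a YAML config file
#'   (see [read_session_config()]).
#' @param out_dir Output directory for the log bundles and manifest.
#' @param seed Integer seed; if `NULL`, a `seed` key in the config file is
#'   used.
#' @return Invisibly, the list of simulated `guess_log`.
#' @export
cmd_simulate <- function(config, out_dir, seed = NULL) {
  if (is.character(config)) {
    config <- read_session_config(config)
    seed <- seed %||% attr(config, "seed")
  }
  stopifnot(inherits(config, "session_config"))
  ensure_dir(out_dir)
  logs <- simulate_session(config, seed = seed)
  for (log in logs) write_game_log(log, out_dir)
  write_manifest(out_dir, config_snapshot(config), seed)
  message(sprintf("simulated %d games (%d players; %d proposals) -> %s",
                  length(logs), config$n_players,
                  sum(vapply(logs, function(l) nrow(l$events), numeric(1))),
                  out_dir))
  invisible(logs)
}

#' Analyze a directory of game logs
#'
#' Computes the full descriptive report: per-game and per-topology accuracy
#' curves, activity histogram, exponential inter-proposal fit, end-of-game
#' Hamming distances, correctness by distance to the closest source, source
#' fidelity, adaptation summary, and (when both topologies have at least
#' two games) the per-second topology comparison tests. One CSV per report.
#'
#' @param log_dir Directory of bundles written by [cmd_simulate()] /
#'   [write_game_log()].
#' @param out_dir Output directory.
#' @return Invisibly, the list of computed reports.
#' @export
cmd_analyze <- function(log_dir, out_dir) {
  logs <- read_log_dir(log_dir)
  ensure_dir(out_dir)
  topo <- vapply(logs, function(l) l$network$topology, character(1))
  curves <- lapply(logs, accuracy_curve)

  acc <- do.call(rbind, lapply(names(logs), function(id) {
    cbind(game_id = id, topology = logs[[id]]$network$topology, curves[[id]])
  }))
  utils::write.csv(acc, file.path(out_dir, "accuracy_curves.csv"), row.names = FALSE)

  agg <- do.call(rbind, lapply(unique(topo), function(tp) {
    cbind(topology = tp, aggregate_curves(curves[topo == tp]))
  }))
  utils::write.csv(agg, file.path(out_dir, "accuracy_by_topology.csv"),
                   row.names = FALSE)

  act <- activity_histogram(logs)
  utils::write.csv(act, file.path(out_dir, "activity_histogram.csv"),
                   row.names = FALSE)

  fit <- interproposal_fit(logs)
  utils::write.csv(data.frame(rate_per_s = fit$rate,
                              characteristic_time_s = fit$characteristic_time,
                              n_intervals = fit$n),
                   file.path(out_dir, "interproposal_fit.csv"), row.names = FALSE)

  ham <- data.frame(game_id = names(logs), topology = topo,
                    end_hamming = vapply(logs, end_hamming, numeric(1)))
  utils::write.csv(ham, file.path(out_dir, "hamming.csv"), row.names = FALSE)

  dist_rep <- correctness_by_distance(logs)
  utils::write.csv(cbind(dist_rep$aggregate,
                         ratio_d1_d2 = dist_rep$ratio,
                         advantage_pct = dist_rep$advantage_pct),
                   file.path(out_dir, "distance_report.csv"), row.names = FALSE)

  fid <- source_fidelity(logs)
  utils::write.csv(as.data.frame(fid), file.path(out_dir, "source_fidelity.csv"),
                   row.names = FALSE)

  adapt <- NULL
  if (length(logs) >= 2) {
    adapt <- adaptation_summary(logs)
    utils::write.csv(adapt, file.path(out_dir, "adaptation.csv"),
                     row.names = FALSE)
  } else {
    message("adaptation summary skipped: need a session with >= 2 games")
  }

  reports <- list(accuracy = acc, accuracy_by_topology = agg, activity = act,
                  interproposal = fit, hamming = ham, distance = dist_rep,
                  fidelity = fid, adaptation = adapt)

  both <- c("regular_lattice", "random_regular")
  if (all(vapply(both, function(tp) sum(topo == tp) >= 2, logical(1)))) {
    cmp <- compare_topologies(curves[topo == both[1]], curves[topo == both[2]])
    utils::write.csv(cmp$table, file.path(out_dir, "topology_comparison.csv"),
                     row.names = FALSE)
    reports$topology_comparison <- cmp
  } else {
    message("topology comparison skipped: need >= 2 games per topology")
  }
  write_manifest(out_dir, list(log_dir = log_dir), NULL,
                 inputs = list.files(log_dir, full.names = TRUE))
  invisible(reports)
}

#' Estimate transition tables and fit the Bayesian model
#'
#' Extracts transition events from every game in `log_dir`, estimates the
#' empirical transition table, and fits the uniform-prior (one-parameter)
#' and current-state-prior (two-parameter) models by grid-search RMSE.
#'
#' @inheritParams cmd_analyze
#' @param s_grid,a_grid Parameter grids (see [fit_one_param()],
#'   [fit_two_param()]).
#' @param min_events Minimum number of transition events required.
#' @return Invisibly, list with `events`, `table`, `fit1`, `fit2`.
#' @export
cmd_fit <- function(log_dir, out_dir, s_grid = seq(0.05, 2, by = 0.01),
                    a_grid = seq(0.05, 2, by = 0.01), min_events = 100) {
  logs <- read_log_dir(log_dir)
  ensure_dir(out_dir)
  events <- do.call(rbind, lapply(logs, extract_transitions))
  if (nrow(events) < min_events) {
    stop_("too few transition events: ", nrow(events), " < ", min_events)
  }
  k <- max(vapply(logs, function(l) l$network$k, numeric(1)))
  table <- transition_table(events, k = k)
  utils::write.csv(as.data.frame(table),
                   file.path(out_dir, "transition_table.csv"), row.names = FALSE)
  utils::write.csv(table$config_weights,
                   file.path(out_dir, "config_weights.csv"), row.names = FALSE)
  fit1 <- fit_one_param(table, s_grid = s_grid)
  fit2 <- fit_two_param(table, s_grid = s_grid, a_grid = a_grid)
  utils::write.csv(as.data.frame(fit1), file.path(out_dir, "rmse_one_param.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(fit2), file.path(out_dir, "rmse_two_param.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(n_events = nrow(events),
         one_param = list(s = fit1$s_opt, rmse = fit1$rmse_opt),
         two_param = list(s = fit2$s_opt, a = fit2$a_opt, rmse = fit2$rmse_opt)),
    file.path(out_dir, "fit_summary.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE
  )
  write_manifest(out_dir, list(log_dir = log_dir, min_events = min_events), NULL,
                 inputs = list.files(log_dir, full.names = TRUE))
  invisible(list(events = events, table = table, fit1 = fit1, fit2 = fit2))
}

#' Run the decision-rule comparison and write its report
#'
#' @param config A [session_config()] or YAML config path giving the matched
#'   conditions.
#' @param out_dir Output directory.
#' @param rules Named list of [decision_rule()]s; defaults to majority,
#'   voter, random and the Bayesian rule of the config's first game.
#' @param n_realizations Realizations per rule per topology.
#' @param seed Integer seed.
#' @return Invisibly, the `comparison_report`.
#' @export
cmd_compare <- function(config, out_dir, rules = NULL, n_realizations = 50,
                        seed = NULL) {
  if (is.character(config)) {
    config <- read_session_config(config)
    seed <- seed %||% attr(config, "seed")
  }
  stopifnot(inherits(config, "session_config"))
  ensure_dir(out_dir)
  if (is.null(rules)) {
    rules <- list(majority = decision_rule("majority"),
                  voter = decision_rule("voter"),
                  random = decision_rule("random"))
    first <- config$rules[[1]]
    if (first$name == "bayesian") rules$bayesian <- first
  }
  report <- run_comparison(config, rules, n_realizations = n_realizations,
                           seed = seed)
  utils::write.csv(report$end, file.path(out_dir, "end_accuracy.csv"),
                   row.names = FALSE)
  long <- do.call(rbind, lapply(names(report$curves), function(tp) {
    do.call(rbind, lapply(names(report$curves[[tp]]), function(rn) {
      cbind(topology = tp, rule = rn, report$curves[[tp]][[rn]])
    }))
  }))
  utils::write.csv(long, file.path(out_dir, "mean_curves.csv"), row.names = FALSE)
  utils::write.csv(rank_rules(report), file.path(out_dir, "rule_ranking.csv"),
                   row.names = FALSE)
  write_manifest(out_dir, c(config_snapshot(config),
                            list(n_realizations = n_realizations)), seed)
  invisible(report)
}
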