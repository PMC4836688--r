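# Canonical on-disk representation of a game: four comma-separated UTF-8
# tables with header rows, named <game_id>_events.csv (player_id, time_s,
# code), <game_id>_edges.csv (from, to), <game_id>_reveals.csv (player_id,
# position, color) and <game_id>_meta.csv (one row of scalar metadata).
# Positions are 1-based; codes are serialized as L-character strings; times
# are seconds from game start written with 17 significant digits so that
# write -> read -> write round-trips bit-exactly.

fmt_time <- function(x) sprintf("%.17g", x)

#' Write a game log as a plain-text file bundle
#'
#' @param log A `guess_log`.
#' @param directory Output directory (created if missing).
#' @param game_id File-name prefix; defaults to the log's own id.
#' @return Invisibly, the character vector of files written.
#' @export
write_game_log <- function(log, directory, game_id = log$game_id) {
  validate_log(log)
  if (!dir.exists(directory)) {
    ok <- dir.create(directory, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop_("cannot create directory: ", directory)
  }
  setup <- log$setup
  paths <- file.path(directory, paste0(game_id, "_",
                                       c("events", "edges", "reveals", "meta"),
                                       ".csv"))
  names(paths) <- c("events", "edges", "reveals", "meta")
  events <- data.frame(player_id = log$events$player,
                       time_s = fmt_time(log$events$time_s),
                       code = log$events$code)
  reveals <- do.call(rbind, lapply(seq_len(setup$n_players), function(j) {
    rv <- setup$reveals[[j]]
    data.frame(player_id = j, position = rv, color = setup$target[rv])
  }))
  meta <- data.frame(
    game_id = game_id, n_players = setup$n_players, k = log$network$k,
    topology = log$network$topology, L = setup$L, n_colors = setup$n_colors,
    reveals_per_player = setup$reveals_per_player,
    duration_s = setup$duration_s,
    proposal_rate_per_s = setup$proposal_rate_per_s,
    target = code_to_string(setup$target), provenance = log$provenance
  )
  tryCatch({
    utils::write.csv(events, paths["events"], row.names = FALSE, quote = FALSE)
    utils::write.csv(as.data.frame(log$network$edges), paths["edges"],
                     row.names = FALSE, quote = FALSE)
    utils::write.csv(reveals, paths["reveals"], row.names = FALSE, quote = FALSE)
    utils::write.csv(meta, paths["meta"], row.names = FALSE, quote = FALSE)
  }, error = function(e) stop_("cannot write game bundle under ", directory,
                               ": ", conditionMessage(e)))
  invisible(paths)
}

#' Read a game log from a plain-text file bundle
#'
#' Events may be stored out of time order; they are re-sorted provided each
#' player's times remain strictly increasing, otherwise reading fails.
#' Malformed rows (bad symbols, wrong code length) are rejected with
#' row-numbered errors, never skipped.
#'
#' @param directory Directory containing the bundle.
#' @param game_id File-name prefix of the game.
#' @return A validated `guess_log`.
#' @export
read_game_log <- function(directory, game_id) {
  path <- function(part) file.path(directory, paste0(game_id, "_", part, ".csv"))
  for (part in c("events", "edges", "reveals", "meta")) {
    if (!file.exists(path(part))) stop_("missing file: ", path(part))
  }
  meta <- utils::read.csv(path("meta"), stringsAsFactors = FALSE)
  L <- meta$L; alphabet <- code_alphabet(meta$n_colors)
  target <- string_to_code(meta$target, L = L, alphabet = alphabet)

  edges <- as.matrix(utils::read.csv(path("edges")))
  network <- structure(
    list(n_nodes = as.integer(meta$n_players), k = as.integer(meta$k),
         topology = meta$topology, edges = canonical_edges(edges)),
    class = "guess_network"
  )
  validate_network(network)

  rv_df <- utils::read.csv(path("reveals"), stringsAsFactors = FALSE)
  if (any(rv_df$position < 1 | rv_df$position > L)) {
    stop_("reveals: position outside 1..", L)
  }
  if (any(!rv_df$player_id %in% seq_len(meta$n_players))) {
    stop_("reveals: player_id outside 1..", meta$n_players)
  }
  reveals <- lapply(seq_len(meta$n_players), function(j) {
    sort(rv_df$position[rv_df$player_id == j])
  })
  if (!setequal(unlist(reveals), seq_len(L))) {
    stop_("reveals do not cover all positions 1..", L)
  }

  ev <- utils::read.csv(path("events"),
                        colClasses = c("integer", "numeric", "character"))
  for (i in seq_len(nrow(ev))) {
    code <- strsplit(ev$code[i], "")[[1]]
    if (length(code) != L) {
      stop_("events row ", i, ": code has length ", length(code), ", expected ", L)
    }
    bad <- setdiff(code, alphabet)
    if (length(bad)) {
      stop_("events row ", i, ": invalid symbol '", bad[1], "' in code")
    }
    if (!ev$player_id[i] %in% seq_len(meta$n_players)) {
      stop_("events row ", i, ": unknown player_id ", ev$player_id[i])
    }
    if (is.na(ev$time_s[i]) || ev$time_s[i] < 0 || ev$time_s[i] > meta$duration_s) {
      stop_("events row ", i, ": time_s outside [0, ", meta$duration_s, "]")
    }
  }
  ord <- order(ev$time_s)
  ev <- ev[ord, ]
  for (j in unique(ev$player_id)) {
    tj <- ev$time_s[ev$player_id == j]
    if (any(diff(tj) <= 0)) {
      stop_("events: times for player ", j, " are not strictly increasing")
    }
  }

  setup <- structure(
    list(target = target, reveals = reveals,
         n_players = as.integer(meta$n_players), L = as.integer(L),
         n_colors = as.integer(meta$n_colors), alphabet = alphabet,
         reveals_per_player = as.integer(meta$reveals_per_player),
         duration_s = as.numeric(meta$duration_s),
         proposal_rate_per_s = as.numeric(meta$proposal_rate_per_s)),
    class = "guess_setup"
  )
  log <- structure(
    list(setup = setup, network = network,
         events = data.frame(player = ev$player_id, time_s = ev$time_s,
                             code = ev$code),
         game_id = meta$game_id, provenance = meta$provenance),
    class = "guess_log"
  )
  validate_log(log)
  log
}

validate_log <- function(log) {
  stopifnot(inherits(log, "guess_log"))
  setup <- log$setup
  ev <- log$events
  if (any(!ev$player %in% seq_len(log$network$n_nodes))) {
    stop_("event player outside the network node set")
  }
  if (setup$n_players != log$network$n_nodes) {
    stop_("setup/network player count mismatch")
  }
  if (nrow(ev)) {
    if (any(ev$time_s < 0 | ev$time_s > setup$duration_s)) {
      stop_("event time outside [0, duration_s]")
    }
    if (is.unsorted(ev$time_s)) stop_("events are not globally time-ordered")
    for (j in unique(ev$player)) {
      tj <- ev$time_s[ev$player == j]
      if (any(diff(tj) <= 0)) {
        stop_("times for player ", j, " are not strictly increasing")
      }
    }
    for (i in seq_len(nrow(ev))) {
      validate_code(strsplit(ev$code[i], "")[[1]], L = setup$L,
                    alphabet = setup$alphabet)
    }
  }
  invisible(log)
}

#' List and read all game bundles in a directory
#'
#' @param directory Directory holding bundles written by [write_game_log()].
#' @return Named list of `guess_log`, keyed by game id, in id order.
#' @export
read_log_dir <- function(directory) {
  metas <- list.files(directory, pattern = "_meta\\.csv$")
  if (!length(metas)) stop_("no game bundles (*_meta.csv) found in ", directory)
  ids <- sort(sub("_meta\\.csv$", "", metas))
  stats::setNames(lapply(ids, function(id) read_game_log(directory, id)), ids)
}

#' Adapt an external ZIP archive of game logs
#'
#' Best-effort bridge for externally deposited experiment archives whose
#' internal layout is undocumented. If the archive already contains the
#' canonical bundle files the identity mapping is applied; otherwise an
#' explicit `mapping` configuration must name the files and columns, and
#' the function fails closed with a "mapping required" error rather than
#' guessing.
#'
#' @param path Path to a ZIP archive.
#' @param mapping Optional list describing the layout: fields
#'   `events_file`, `player_col`, `time_col`, `code_col` plus the canonical
#'   companion files `edges_file`, `reveals_file`, `meta_file`.
#' @param exdir Extraction directory.
#' @return Named list of `guess_log`.
#' @export
adapt_external_archive <- function(path, mapping = NULL,
                                   exdir = tempfile("archive")) {
  if (!file.exists(path)) stop_("archive not found: ", path)
  listing <- utils::unzip(path, list = TRUE)$Name
  canonical <- any(grepl("_meta\\.csv$", listing))
  if (!canonical && is.null(mapping)) {
    stop_("mapping required: archive layout is not the canonical schema; ",
          "supply a mapping config naming the event/network/reveal files ",
          "and their columns")
  }
  utils::unzip(path, exdir = exdir)
  if (canonical) {
    dirs <- unique(dirname(file.path(exdir, grep("_meta\\.csv$", listing, value = TRUE))))
    out <- list()
    for (d in dirs) out <- c(out, read_log_dir(d))
    return(out)
  }
  required <- c("events_file", "player_col", "time_col", "code_col",
                "edges_file", "reveals_file", "meta_file")
  missing <- setdiff(required, names(mapping))
  if (length(missing)) {
    stop_("mapping required: unmapped fields: ", paste(missing, collapse = ", "))
  }
  ev <- utils::read.csv(file.path(exdir, mapping$events_file),
                        stringsAsFactors = FALSE)
  for (col in c(mapping$player_col, mapping$time_col, mapping$code_col)) {
    if (!col %in% names(ev)) {
      stop_("mapping names column '", col, "' absent from ", mapping$events_file)
    }
  }
  # rewrite to a canonical bundle alongside the mapped companions, then read
  meta <- utils::read.csv(file.path(exdir, mapping$meta_file),
                          stringsAsFactors = FALSE)
  id <- meta$game_id[1]
  canon <- data.frame(player_id = ev[[mapping$player_col]],
                      time_s = fmt_time(ev[[mapping$time_col]]),
                      code = ev[[mapping$code_col]])
  dir.create(file.path(exdir, "canonical"), showWarnings = FALSE)
  utils::write.csv(canon, file.path(exdir, "canonical", paste0(id, "_events.csv")),
                   row.names = FALSE, quote = FALSE)
  file.copy(file.path(exdir, mapping$edges_file),
            file.path(exdir, "canonical", paste0(id, "_edges.csv")))
  file.copy(file.path(exdir, mapping$reveals_file),
            file.path(exdir, "canonical", paste0(id, "_reveals.csv")))
  file.copy(file.path(exdir, mapping$meta_file),
            file.path(exdir, "canonical", paste0(id, "_meta.csv")))
  read_log_dir(file.path(exdir, "canonical"))
}
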