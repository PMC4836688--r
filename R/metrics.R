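#' Latest code a player holds at a given time
#'
#' Proposal state carries forward between submissions: a player's code at
#' time `t` is their most recent proposal at or before `t`.
#'
#' @param log A `guess_log`.
#' @param player Player id (1-based node index).
#' @param t Time in seconds, `>= 0`.
#' @return The code as an `L`-character string, or `NA` if the player has
#'   not proposed by `t`.
#' @export
latest_code_at <- function(log, player, t) {
  stopifnot(inherits(log, "guess_log"))
  if (!player %in% seq_len(log$setup$n_players)) stop_("unknown player: ", player)
  if (t < 0) stop_("t must be >= 0")
  ev <- log$events[log$events$player == player, ]
  i <- sum(ev$time_s <= t)
  if (i == 0) NA_character_ else ev$code[i]
}

# Per-player step functions of the number of correct positions, evaluated
# on the 1-second grid. Returns an n_players x length(grid) matrix with NA
# before a player's first proposal.
correct_count_matrix <- function(log, grid) {
  setup <- log$setup
  target <- setup$target
  n <- setup$n_players
  M <- matrix(NA_real_, nrow = n, ncol = length(grid))
  for (j in seq_len(n)) {
    ev <- log$events[log$events$player == j, ]
    if (!nrow(ev)) next
    ncorr <- vapply(strsplit(ev$code, ""), function(code) sum(code == target),
                    numeric(1))
    idx <- findInterval(grid, ev$time_s)  # proposal at t counts from t onward
    M[j, ] <- c(NA_real_, ncorr)[idx + 1]
  }
  M
}

#' Group accuracy trajectory p(t)
#'
#' At each second of the game, the mean over all `N` players of the number
#' of positions of their latest proposal matching the target. By default
#' players that have not proposed yet contribute 0 correct positions (the
#' group mean keeps `N` fixed); `absent = "exclude"` instead averages over
#' players with at least one proposal.
#'
#' @param log A `guess_log`.
#' @param absent `"zero"` (default) or `"exclude"`.
#' @return Object of class `performance_curve`: a data frame with columns
#'   `time` (0 to `duration_s`, 1 s steps) and `p`; the per-player integer
#'   trajectories are attached as attribute `"per_player"`.
#' @export
accuracy_curve <- function(log, absent = c("zero", "exclude")) {
  absent <- match.arg(absent)
  stopifnot(inherits(log, "guess_log"))
  grid <- 0:floor(log$setup$duration_s)
  M <- correct_count_matrix(log, grid)
  p <- if (absent == "zero") {
    colMeans(replace(M, is.na(M), 0))
  } else {
    out <- colMeans(M, na.rm = TRUE)
    replace(out, is.nan(out), 0)
  }
  out <- data.frame(time = grid, p = p)
  attr(out, "per_player") <- M
  class(out) <- c("performance_curve", "data.frame")
  out
}

#' Pointwise mean of accuracy curves
#'
#' Aggregates games with the same interaction topology by averaging their
#' `p(t)` curves at each grid second.
#'
#' @param curves List of [accuracy_curve()] results on a common grid.
#' @return A `performance_curve` data frame.
#' @export
aggregate_curves <- function(curves) {
  stopifnot(length(curves) >= 1)
  p <- rowMeans(vapply(curves, function(cv) cv$p, numeric(nrow(curves[[1]]))))
  out <- data.frame(time = curves[[1]]$time, p = p)
  class(out) <- c("performance_curve", "data.frame")
  out
}

interproposal_intervals <- function(logs) {
  logs <- as_log_list(logs)
  unlist(lapply(logs, function(log) {
    unlist(lapply(split(log$events$time_s, log$events$player), function(t) {
      if (length(t) >= 2) diff(t) else numeric(0)
    }), use.names = FALSE)
  }), use.names = FALSE)
}

as_log_list <- function(logs) {
  if (inherits(logs, "guess_log")) list(logs) else logs
}

#' Exponential fit to inter-proposal times
#'
#' Pools consecutive same-player proposal time differences across games and
#' fits the exponential rate by closed-form maximum likelihood,
#' `b = 1 / mean(intervals)` (no iterative fitting). The complementary
#' cumulative distribution at 1 s bins is attached for plotting.
#'
#' @param logs A `guess_log` or list of them.
#' @return Object of class `exp_fit`: list with `rate` (per second),
#'   `characteristic_time` (`1/rate`, seconds), `n` intervals, and a `ccdf`
#'   data frame (`t`, `ccdf`).
#' @export
interproposal_fit <- function(logs) {
  iv <- interproposal_intervals(logs)
  if (!length(iv)) stop_("no inter-proposal intervals (need >= 2 proposals for some player)")
  rate <- 1 / mean(iv)
  t_bins <- 0:ceiling(max(iv))
  ccdf <- vapply(t_bins, function(t) mean(iv > t), numeric(1))
  structure(
    list(rate = rate, characteristic_time = 1 / rate, n = length(iv),
         ccdf = data.frame(t = t_bins, ccdf = ccdf)),
    class = "exp_fit"
  )
}

#' @export
print.exp_fit <- function(x, ...) {
  cat(sprintf("<exp_fit> rate b = %.4f /s (characteristic time %.1f s, n = %d)\n",
              x$rate, x$characteristic_time, x$n))
  invisible(x)
}

#' Temporal activity histogram
#'
#' Counts proposals per time bin, pooled across games.
#'
#' @param logs A `guess_log` or list of them.
#' @param bin_s Bin width in seconds (default 5).
#' @return Data frame with columns `bin_start`, `bin_end`, `count`; the mean
#'   count per bin is attached as attribute `"mean_per_bin"`.
#' @export
activity_histogram <- function(logs, bin_s = 5) {
  logs <- as_log_list(logs)
  duration <- max(vapply(logs, function(l) l$setup$duration_s, numeric(1)))
  breaks <- seq(0, ceiling(duration / bin_s) * bin_s, by = bin_s)
  times <- unlist(lapply(logs, function(l) l$events$time_s), use.names = FALSE)
  count <- if (length(times)) {
    tabulate(findInterval(times, breaks, left.open = TRUE,
                          rightmost.closed = TRUE),
             nbins = length(breaks) - 1)
  } else {
    rep(0L, length(breaks) - 1)
  }
  out <- data.frame(bin_start = breaks[-length(breaks)], bin_end = breaks[-1],
                    count = count)
  attr(out, "mean_per_bin") <- mean(count)
  out
}

#' Mean pairwise Hamming distance at the end of a game
#'
#' Averages the Hamming distance over all unordered pairs of players' final
#' codes (latest proposal at `duration_s`); players with no proposal are
#' excluded from the pairs.
#'
#' @param log A `guess_log`.
#' @return Mean pairwise distance, in `[0, L]`.
#' @export
end_hamming <- function(log) {
  stopifnot(inherits(log, "guess_log"))
  finals <- vapply(seq_len(log$setup$n_players), function(j) {
    latest_code_at(log, j, log$setup$duration_s)
  }, character(1))
  finals <- finals[!is.na(finals)]
  if (length(finals) < 2) stop_("need >= 2 players with proposals")
  pairs <- utils::combn(length(finals), 2)
  mean(vapply(seq_len(ncol(pairs)), function(i) {
    hamming_distance(finals[pairs[1, i]], finals[pairs[2, i]])
  }, numeric(1)))
}

#' Hop distance from every player to the nearest source of a position
#'
#' For a given code position, a node is a source if that position was
#' revealed to the player at that node. Distances are breadth-first
#' shortest-path hop counts; sources have distance 0.
#'
#' @param network A `guess_network`.
#' @param reveals List of revealed-position vectors, one per player.
#' @param position Code position (1-based).
#' @return Integer vector of distances, one per player.
#' @export
source_distance <- function(network, reveals, position) {
  stopifnot(inherits(network, "guess_network"))
  src <- which(vapply(reveals, function(rv) position %in% rv, logical(1)))
  if (!length(src)) stop_("position ", position, " has no source (coverage violated)")
  g <- as_igraph(network)
  d <- igraph::distances(g, v = seq_len(network$n_nodes), to = src)
  out <- apply(d, 1, min)
  if (any(!is.finite(out))) stop_("network is disconnected")
  as.integer(out)
}

#' Largest player-to-source distance over all unknown positions
#'
#' @param log A `guess_log` (its network and reveal assignment are used).
#' @return Integer: the maximum over players and their unknown positions of
#'   the distance to the closest source.
#' @export
max_source_distance <- function(log) {
  stopifnot(inherits(log, "guess_log"))
  L <- log$setup$L
  m <- 0L
  for (pos in seq_len(L)) {
    d <- source_distance(log$network, log$setup$reveals, pos)
    unknown <- vapply(log$setup$reveals, function(rv) !(pos %in% rv), logical(1))
    if (any(unknown)) m <- max(m, max(d[unknown]))
  }
  m
}

#' Correctness of unknown positions by distance to the closest source
#'
#' For every (player, unknown position) cell, classified by its hop distance
#' to the nearest source, the fraction of grid seconds at which the player's
#' current color equals the target. Cells of players that have not proposed
#' yet count as incorrect (consistent with [accuracy_curve()]'s default).
#' The advantage ratio divides the whole-game pooled fraction at distance 1
#' by the fraction at distance 2 (pooling before dividing avoids unstable
#' early-game ratios).
#'
#' @param logs A `guess_log` or list of them; fractions are pooled across
#'   games.
#' @return Object of class `distance_report`: list with `by_time` (data
#'   frame `time`, `d`, `fraction`), `aggregate` (data frame `d`,
#'   `fraction`, `n_cells`), `ratio` (fraction at d = 1 over d = 2; `NA` if
#'   either side undefined) and `advantage_pct` (`100 * (ratio - 1)`).
#' @export
correctness_by_distance <- function(logs) {
  logs <- as_log_list(logs)
  acc <- list()  # per distance: num/den per time
  n_cells <- integer(0)
  grid <- 0:floor(logs[[1]]$setup$duration_s)
  for (log in logs) {
    setup <- log$setup
    L <- setup$L
    D <- vapply(seq_len(L), function(pos) {
      source_distance(log$network, setup$reveals, pos)
    }, integer(setup$n_players))
    for (j in seq_len(setup$n_players)) {
      ev <- log$events[log$events$player == j, ]
      codes <- if (nrow(ev)) do.call(rbind, strsplit(ev$code, "")) else NULL
      idx <- if (nrow(ev)) findInterval(grid, ev$time_s) else rep(0L, length(grid))
      unknown <- setdiff(seq_len(L), setup$reveals[[j]])
      for (pos in unknown) {
        d <- as.character(D[j, pos])
        corr <- if (is.null(codes)) {
          rep(0, length(grid))
        } else {
          c(0, as.numeric(codes[, pos] == setup$target[pos]))[idx + 1]
        }
        if (is.null(acc[[d]])) {
          acc[[d]] <- list(num = numeric(length(grid)), den = numeric(length(grid)))
          n_cells[d] <- 0L
        }
        acc[[d]]$num <- acc[[d]]$num + corr
        acc[[d]]$den <- acc[[d]]$den + 1
        n_cells[d] <- n_cells[d] + 1L
      }
    }
  }
  ds <- sort(as.integer(names(acc)))
  by_time <- do.call(rbind, lapply(ds, function(d) {
    a <- acc[[as.character(d)]]
    data.frame(time = grid, d = d, fraction = a$num / a$den)
  }))
  # pooled fraction per distance: total correct cell-seconds / total cell-seconds
  aggregate <- data.frame(
    d = ds,
    fraction = vapply(ds, function(d) {
      a <- acc[[as.character(d)]]
      sum(a$num) / (a$den[1] * length(grid))
    }, numeric(1)),
    n_cells = as.integer(n_cells[as.character(ds)])
  )
  f1 <- aggregate$fraction[match(1L, aggregate$d)]
  f2 <- aggregate$fraction[match(2L, aggregate$d)]
  ratio <- if (is.na(f1) || is.na(f2) || length(f1) == 0) NA_real_ else f1 / f2
  structure(
    list(by_time = by_time, aggregate = aggregate, ratio = ratio,
         advantage_pct = 100 * (ratio - 1)),
    class = "distance_report"
  )
}

#' @export
print.distance_report <- function(x, ...) {
  cat("<distance_report>\n")
  print(x$aggregate)
  cat(sprintf("ratio d=1 / d=2: %.3f (advantage %.1f%%)\n", x$ratio, x$advantage_pct))
  invisible(x)
}

#' Fidelity of revealed positions across proposals
#'
#' Over all proposals, the fraction of revealed-position cells set to the
#' true color, and the number of changes: a change is a pair of consecutive
#' proposals by one player that differ at one of that player's revealed
#' positions (counted per differing position).
#'
#' @param logs A `guess_log` or list of them.
#' @return List with `fraction_correct`, `n_changes`, `n_proposals`.
#' @export
source_fidelity <- function(logs) {
  logs <- as_log_list(logs)
  n_cells <- 0L; n_correct <- 0L; n_changes <- 0L; n_proposals <- 0L
  for (log in logs) {
    setup <- log$setup
    n_proposals <- n_proposals + nrow(log$events)
    for (j in seq_len(setup$n_players)) {
      ev <- log$events[log$events$player == j, ]
      if (!nrow(ev)) next
      rv <- setup$reveals[[j]]
      codes <- do.call(rbind, strsplit(ev$code, ""))
      truth <- matrix(setup$target[rv], nrow = nrow(ev), ncol = length(rv),
                      byrow = TRUE)
      n_cells <- n_cells + length(rv) * nrow(ev)
      n_correct <- n_correct + sum(codes[, rv, drop = FALSE] == truth)
      if (nrow(ev) >= 2) {
        a <- codes[-nrow(ev), rv, drop = FALSE]
        b <- codes[-1, rv, drop = FALSE]
        n_changes <- n_changes + sum(a != b)
      }
    }
  }
  list(fraction_correct = if (n_cells) n_correct / n_cells else NA_real_,
       n_changes = n_changes, n_proposals = n_proposals)
}

#' End-of-game score of one player
#'
#' The game rewards 10 points for finishing, 100 points per correct
#' position, and a 1000-point bonus for guessing the entire code.
#'
#' @param final_code Player's final complete code (string or vector).
#' @param target Target code.
#' @param finished Whether the player finished the game.
#' @return Points (numeric).
#' @export
game_score <- function(final_code, target, finished = TRUE) {
  if (is.character(final_code) && length(final_code) == 1) {
    final_code <- strsplit(final_code, "")[[1]]
  }
  if (is.character(target) && length(target) == 1) {
    target <- strsplit(target, "")[[1]]
  }
  ncorrect <- sum(final_code == target)
  10 * as.numeric(finished) + 100 * ncorrect +
    1000 * as.numeric(ncorrect == length(target))
}

#' Per-second rank tests between two sets of accuracy curves
#'
#' At each 1 s grid step, compares the per-game `p(t)` values of two
#' topologies with the unpaired two-sided Mann-Whitney U test and (when a
#' pairing is available, i.e. equal game counts) the paired two-sided
#' Wilcoxon signed-rank test. Steps at which the values carry no evidence
#' (all equal, or all paired differences zero) are reported with p-value 1
#' and flagged.
#'
#' @param curves_a,curves_b Lists of [accuracy_curve()] results (one per
#'   game) on a common grid; `curves_b[[i]]` is the pair of
#'   `curves_a[[i]]` for the paired test.
#' @return List with `table` (data frame `time`, `p_unpaired`, `p_paired`,
#'   `degenerate`), `mean_p_unpaired`, `mean_p_paired`.
#' @export
compare_topologies <- function(curves_a, curves_b) {
  if (length(curves_a) < 2 || length(curves_b) < 2) {
    stop_("need >= 2 games per topology")
  }
  grid <- curves_a[[1]]$time
  A <- vapply(curves_a, function(cv) cv$p, numeric(length(grid)))
  B <- vapply(curves_b, function(cv) cv$p, numeric(length(grid)))
  paired <- length(curves_a) == length(curves_b)
  res <- t(vapply(seq_along(grid), function(i) {
    x <- A[i, ]; y <- B[i, ]
    degenerate <- FALSE
    if (length(unique(c(x, y))) == 1) {
      pu <- 1; degenerate <- TRUE
    } else {
      pu <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE)$p.value)
    }
    pp <- NA_real_
    if (paired) {
      if (all(x == y)) {
        pp <- 1; degenerate <- TRUE
      } else {
        pp <- suppressWarnings(stats::wilcox.test(x, y, paired = TRUE,
                                                  exact = FALSE)$p.value)
      }
    }
    c(pu, pp, degenerate)
  }, numeric(3)))
  table <- data.frame(time = grid, p_unpaired = res[, 1], p_paired = res[, 2],
                      degenerate = as.logical(res[, 3]))
  list(table = table,
       mean_p_unpaired = mean(table$p_unpaired),
       mean_p_paired = if (paired) mean(table$p_paired) else NA_real_)
}

#' Per-game mean inter-proposal time across a session
#'
#' Quantifies adaptation: players getting faster shows up as a smaller mean
#' inter-proposal time in later games.
#'
#' @param session_logs List of `guess_log`, in game order.
#' @return Data frame with columns `game`, `game_id`, `mean_interproposal_s`,
#'   `se`, `n_intervals`.
#' @export
adaptation_summary <- function(session_logs) {
  session_logs <- as_log_list(session_logs)
  if (length(session_logs) < 2) stop_("need a session with >= 2 games")
  do.call(rbind, lapply(seq_along(session_logs), function(g) {
    iv <- interproposal_intervals(session_logs[[g]])
    data.frame(
      game = g, game_id = session_logs[[g]]$game_id,
      mean_interproposal_s = if (length(iv)) mean(iv) else NA_real_,
      se = if (length(iv) > 1) stats::sd(iv) / sqrt(length(iv)) else NA_real_,
      n_intervals = length(iv)
    )
  }))
}
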