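#' Extract per-position transition events from a game log
#'
#' For every pair of consecutive proposals by the same player (the first
#' proposal generates no events) and every position unknown to that player,
#' one event records the prior color, the new color, and the number of
#' informative neighbors showing each color. Neighbor states are taken from
#' the neighbors' latest proposals strictly before the deciding proposal's
#' time (a simultaneous neighbor update cannot influence the decision);
#' neighbors with no proposal yet are excluded, so `k_eff <= k`.
#'
#' @param log A `guess_log`.
#' @return Data frame with columns `player`, `position`, `time_s`, `from`,
#'   `to`, `n_R`, `n_B`, `n_Y` (one count column per alphabet color) and
#'   `k_eff`.
#' @export
extract_transitions <- function(log) {
  stopifnot(inherits(log, "guess_log"))
  setup <- log$setup
  alphabet <- setup$alphabet
  L <- setup$L
  adj <- neighbors_of(log$network)
  ev <- log$events
  by_player <- split(seq_len(nrow(ev)), ev$player)
  times <- split(ev$time_s, ev$player)
  codes <- lapply(split(ev$code, ev$player), function(x) {
    do.call(rbind, strsplit(x, ""))
  })
  blocks <- list()
  for (j_chr in names(by_player)) {
    j <- as.integer(j_chr)
    idx <- by_player[[j_chr]]
    if (length(idx) < 2) next
    unknown <- setdiff(seq_len(L), setup$reveals[[j]])
    if (!length(unknown)) next
    tj <- times[[j_chr]]
    cj <- codes[[j_chr]]
    for (e in 2:length(idx)) {
      t2 <- tj[e]
      nb_codes <- lapply(adj[[j]], function(nb) {
        tn <- times[[as.character(nb)]]
        if (is.null(tn)) return(NULL)
        i <- sum(tn < t2)
        if (i == 0) NULL else codes[[as.character(nb)]][i, unknown]
      })
      nb_codes <- nb_codes[!vapply(nb_codes, is.null, TRUE)]
      cnt <- matrix(0L, nrow = length(alphabet), ncol = length(unknown),
                    dimnames = list(alphabet, NULL))
      for (nc in nb_codes) {
        for (m in seq_along(alphabet)) cnt[m, ] <- cnt[m, ] + (nc == alphabet[m])
      }
      block <- list(player = rep(j, length(unknown)), position = unknown,
                    time_s = rep(t2, length(unknown)),
                    from = cj[e - 1, unknown], to = cj[e, unknown])
      for (m in seq_along(alphabet)) {
        block[[paste0("n_", alphabet[m])]] <- cnt[m, ]
      }
      block$k_eff <- rep(length(nb_codes), length(unknown))
      blocks[[length(blocks) + 1]] <- block
    }
  }
  cols <- c("player", "position", "time_s", "from", "to",
            paste0("n_", alphabet), "k_eff")
  if (!length(blocks)) {
    out <- data.frame(player = integer(0), position = integer(0),
                      time_s = numeric(0), from = character(0),
                      to = character(0))
    for (m in alphabet) out[[paste0("n_", m)]] <- integer(0)
    out$k_eff <- integer(0)
    return(out)
  }
  out <- lapply(cols, function(cl) {
    unlist(lapply(blocks, `[[`, cl), use.names = FALSE)
  })
  names(out) <- cols
  as.data.frame(out, stringsAsFactors = FALSE)
}

event_alphabet <- function(events) {
  sub("^n_", "", grep("^n_", names(events), value = TRUE))
}

#' Empirical probability to change to a color
#'
#' For each color `X` and each neighbor count `n`, the conditional
#' probability that a decision ends on `X` (switching to it or remaining on
#' it) given `n` neighbors currently showing `X`:
#' `P(X | n_X) = #(n_X = n, to = X) / #(n_X = n)`. Cells with no events are
#' reported as `NA` (undefined), never 0.
#'
#' @param events Event data frame from [extract_transitions()] (or
#'   [sample_rule_events()]).
#' @param k Largest neighbor count to tabulate (cells `n = 0..k`).
#' @param include_stay If `FALSE`, restrict to strict changes (events with
#'   `from != X`) for sensitivity analysis.
#' @return Data frame with columns `color`, `n`, `p`, `count`.
#' @export
estimate_prob_to_color <- function(events, k = 4, include_stay = TRUE) {
  if (!nrow(events)) stop_("no transition events")
  alphabet <- event_alphabet(events)
  out <- do.call(rbind, lapply(alphabet, function(X) {
    nX <- events[[paste0("n_", X)]]
    keep <- if (include_stay) rep(TRUE, nrow(events)) else events$from != X
    cells(nX[keep], events$to[keep] == X, k, color = X)
  }))
  rownames(out) <- NULL
  out
}

#' Empirical stay and switch probability curves
#'
#' For each final color `X` and neighbor count `n`, the probability of
#' staying on `X` among events whose prior color is `X`
#' (`P(X | X; n_X = n)`) and of switching to `X` among events whose prior
#' color differs (`P(X | not-X; n_X = n)`). The aggregated curves pool
#' events across final colors.
#'
#' @inheritParams estimate_prob_to_color
#' @return List with data frames `stay`, `switch` (columns `color`, `n`,
#'   `p`, `count`) and `stay_agg`, `switch_agg` (columns `n`, `p`, `count`).
#' @export
estimate_conditional <- function(events, k = 4) {
  if (!nrow(events)) stop_("no transition events")
  alphabet <- event_alphabet(events)
  stay <- list(); sw <- list()
  for (X in alphabet) {
    nX <- events[[paste0("n_", X)]]
    is_stay <- events$from == X
    stay[[X]] <- cells(nX[is_stay], events$to[is_stay] == X, k, color = X)
    sw[[X]] <- cells(nX[!is_stay], events$to[!is_stay] == X, k, color = X)
  }
  stay <- do.call(rbind, stay); sw <- do.call(rbind, sw)
  rownames(stay) <- rownames(sw) <- NULL
  list(stay = stay, switch = sw,
       stay_agg = pool_cells(stay), switch_agg = pool_cells(sw))
}

cells <- function(n_values, success, k, color = NULL) {
  n <- 0:k
  count <- vapply(n, function(v) sum(n_values == v), numeric(1))
  hits <- vapply(n, function(v) sum(success[n_values == v]), numeric(1))
  p <- ifelse(count > 0, hits / count, NA_real_)
  if (is.null(color)) {
    data.frame(n = n, p = p, count = count)
  } else {
    data.frame(color = color, n = n, p = p, count = count)
  }
}

pool_cells <- function(df) {
  agg <- stats::aggregate(cbind(hits = ifelse(is.na(df$p), 0, df$p * df$count),
                                count = df$count) ~ n, data = df, FUN = sum)
  agg$p <- ifelse(agg$count > 0, agg$hits / agg$count, NA_real_)
  data.frame(n = agg$n, p = agg$p, count = agg$count)
}

#' Estimate a full empirical transition table
#'
#' Bundles the change-to-color curves ([estimate_prob_to_color()], per color
#' and pooled over colors), the stay/switch curves ([estimate_conditional()]),
#' and the empirical frequencies of full neighbor configurations per prior
#' color (needed to marginalize model predictions over configurations).
#' Aggregation pools events over positions and players, treating positions
#' as independent.
#'
#' @inheritParams estimate_prob_to_color
#' @param min_count Cells with fewer events are flagged `low_count` and
#'   excluded from RMSE fitting by default.
#' @return Object of class `transition_table`.
#' @export
transition_table <- function(events, k = 4, min_count = 5,
                             include_stay = TRUE) {
  if (!nrow(events)) stop_("no transition events")
  alphabet <- event_alphabet(events)
  to_color <- estimate_prob_to_color(events, k = k, include_stay = include_stay)
  cond <- estimate_conditional(events, k = k)
  cw <- stats::aggregate(
    list(count = rep(1L, nrow(events))),
    by = c(list(from = events$from),
           stats::setNames(lapply(alphabet, function(m) events[[paste0("n_", m)]]),
                           paste0("n_", alphabet))),
    FUN = sum
  )
  tab <- list(
    alphabet = alphabet, k = as.integer(k), min_count = as.integer(min_count),
    n_events = nrow(events),
    to_color = flag_low(to_color, min_count),
    to_color_agg = flag_low(pool_cells(to_color), min_count),
    stay = flag_low(cond$stay, min_count),
    switch = flag_low(cond$switch, min_count),
    stay_agg = flag_low(cond$stay_agg, min_count),
    switch_agg = flag_low(cond$switch_agg, min_count),
    config_weights = cw
  )
  structure(tab, class = "transition_table")
}

flag_low <- function(df, min_count) {
  df$low_count <- df$count < min_count
  df
}

#' @export
print.transition_table <- function(x, ...) {
  cat(sprintf("<transition_table> %d events, k = %d, colors %s\n",
              x$n_events, x$k, paste(x$alphabet, collapse = "")))
  invisible(x)
}

#' Export a transition table as one long data frame
#'
#' @param x A `transition_table`.
#' @param ... Unused.
#' @return Data frame with columns `curve`, `color`, `n`, `p`, `count`.
#' @export
as.data.frame.transition_table <- function(x, ...) {
  pieces <- list(
    cbind(curve = "to_color", x$to_color),
    cbind(curve = "to_color_agg", color = "all", x$to_color_agg),
    cbind(curve = "stay", x$stay),
    cbind(curve = "switch", x$switch),
    cbind(curve = "stay_agg", color = "all", x$stay_agg),
    cbind(curve = "switch_agg", color = "all", x$switch_agg)
  )
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}
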