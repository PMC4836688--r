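#' Decision rules for a single code position
#'
#' A decision rule maps a player's current color at a position (possibly
#' still unknown) and the colors shown by informative neighbors to a
#' probability distribution over the alphabet:
#'
#' * `"majority"` — the most frequent neighbor color; ties are broken
#'   uniformly among the tied colors.
#' * `"voter"` — a color drawn from the neighborhood. The default
#'   `voter_mode = "weighted"` draws from the multiset of neighbor colors
#'   (the classic voter model); `"distinct"` draws uniformly over the
#'   distinct colors present.
#' * `"random"` — uniform over the full alphabet, ignoring neighbors.
#' * `"bayesian"` — the Bayesian posterior of [bayes_posterior()] with
#'   parameters `s` and `a`; if the player has no current color yet the
#'   uniform-prior form [bayes_posterior_uniform()] is used.
#' * `"empirical_table"` — probabilities looked up from an estimated
#'   [transition_table()], conditioned on the current color by default;
#'   undefined (zero-count) cells fall back to the uniform distribution.
#'
#' Voter and majority fall back to the uniform distribution when no neighbor
#' has proposed yet (neighbors are informative only after their first guess).
#'
#' @param name Rule name.
#' @param s,a Parameters for the `"bayesian"` rule (see [bayes_params()]).
#' @param table A `transition_table` for the `"empirical_table"` rule.
#' @param voter_mode `"weighted"` or `"distinct"` (voter rule only).
#' @param condition_on_prior For `"empirical_table"`: if `TRUE` (default) use
#'   the stay/switch curves conditioned on the current color; if `FALSE` use
#'   the marginal change-to-color curves.
#' @return Object of class `decision_rule`.
#' @export
decision_rule <- function(name = c("majority", "voter", "random", "bayesian",
                                   "empirical_table"),
                          s = NULL, a = NULL, table = NULL,
                          voter_mode = c("weighted", "distinct"),
                          condition_on_prior = TRUE) {
  name <- match.arg(name)
  voter_mode <- match.arg(voter_mode)
  params <- list()
  if (name == "bayesian") {
    if (is.null(s)) stop_("bayesian rule requires parameter s")
    params <- bayes_params(s, a %||% 1)
  } else if (name == "empirical_table") {
    if (!inherits(table, "transition_table")) {
      stop_("empirical_table rule requires a transition_table")
    }
    params <- list(table = table, condition_on_prior = isTRUE(condition_on_prior))
  } else if (name == "voter") {
    params <- list(voter_mode = voter_mode)
  }
  structure(list(name = name, params = params), class = "decision_rule")
}

#' @export
print.decision_rule <- function(x, ...) {
  extra <- switch(x$name,
    bayesian = sprintf(" (s = %g, a = %g)", x$params$s, x$params$a),
    voter = sprintf(" (%s)", x$params$voter_mode),
    "")
  cat(sprintf("<decision_rule> %s%s\n", x$name, extra))
  invisible(x)
}

#' Probability distribution a rule assigns over the colors
#'
#' @param rule A [decision_rule()].
#' @param current The player's current color at the position, or `NA` if the
#'   player has not proposed yet.
#' @param counts Named vector of informative-neighbor counts per color.
#' @return Named probability vector over `names(counts)`, summing to 1.
#' @export
rule_distribution <- function(rule, current, counts) {
  stopifnot(inherits(rule, "decision_rule"))
  check_counts(counts)
  alphabet <- names(counts)
  uniform <- stats::setNames(rep(1 / length(alphabet), length(alphabet)), alphabet)
  total <- sum(counts)
  switch(rule$name,
    random = uniform,
    majority = {
      if (total == 0) return(uniform)
      top <- counts == max(counts)
      stats::setNames(as.numeric(top) / sum(top), alphabet)
    },
    voter = {
      if (total == 0) return(uniform)
      if (rule$params$voter_mode == "weighted") {
        counts / total
      } else {
        present <- counts > 0
        stats::setNames(as.numeric(present) / sum(present), alphabet)
      }
    },
    bayesian = {
      if (is.na(current)) {
        bayes_posterior_uniform(counts, rule$params$s)
      } else {
        bayes_posterior(counts, current, rule$params$s, rule$params$a)
      }
    },
    empirical_table = table_distribution(rule$params$table, current, counts,
                                         rule$params$condition_on_prior),
    stop_("unknown rule: ", rule$name)
  )
}

# Empirical-table lookup: relative weight of color X is the estimated
# probability of ending on X given the conditioning cell at n = counts[X];
# weights are renormalized over the alphabet. Any undefined cell falls back
# to the uniform distribution.
table_distribution <- function(table, current, counts, condition_on_prior) {
  alphabet <- names(counts)
  n_cap <- pmin(counts, table$k)  # clamp to the table's degree range
  w <- vapply(alphabet, function(X) {
    n <- n_cap[[X]]
    if (is.na(current) || !condition_on_prior) {
      lookup_cell(table$to_color_agg, n)
    } else if (identical(current, X)) {
      lookup_cell(table$stay_agg, n)
    } else {
      lookup_cell(table$switch_agg, n)
    }
  }, numeric(1))
  if (anyNA(w) || sum(w) <= 0) {
    return(stats::setNames(rep(1 / length(alphabet), length(alphabet)), alphabet))
  }
  w / sum(w)
}

lookup_cell <- function(df, n) {
  i <- match(n, df$n)
  if (is.na(i)) NA_real_ else df$p[i]
}

#' Sample one color decision
#'
#' Draws a color from the distribution the rule assigns given the player's
#' current color and the multiset of neighbor colors.
#'
#' @param rule A [decision_rule()].
#' @param current Current color or `NA`.
#' @param neighbor_colors Character vector (multiset) of the colors shown by
#'   neighbors that have already proposed; may be empty.
#' @param alphabet Color alphabet.
#' @return A single color symbol.
#' @export
decide_position <- function(rule, current, neighbor_colors,
                            alphabet = code_alphabet()) {
  bad <- setdiff(neighbor_colors, alphabet)
  if (length(bad)) stop_("neighbor colors outside alphabet: ", paste(bad, collapse = ","))
  counts <- stats::setNames(
    tabulate(match(neighbor_colors, alphabet), nbins = length(alphabet)),
    alphabet
  )
  p <- rule_distribution(rule, current, counts)
  alphabet[sample.int(length(alphabet), 1L, prob = p)]
}
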