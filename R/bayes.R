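#' Bayesian aggregation of neighbor color signals
#'
#' Players are modeled as Bayesian agents that update their belief about a
#' position's color from the colors currently shown by their neighbors. Each
#' neighbor showing color `x` is a signal; a signal matching the true state
#' has likelihood `C0` and a mismatching one `C'`, so only the ratio
#' `s = C'/C0` matters. After observing `n_R, n_B, n_Y` signals, the
#' posterior weight of color `x` is proportional to `s^(-n_x)`.
#'
#' With a uniform prior over colors ([bayes_posterior_uniform()]) this gives
#' `P(X) = 1 / (1 + sum_{x != X} s^(n_X - n_x))`. When the prior instead
#' favors the agent's current color `A` by the odds parameter
#' `a = P_pre(other) / P_pre(current)` ([bayes_posterior()]), the current
#' color's weight is multiplied by `1/a`:
#' `P(X | A = X) = 1 / (1 + a * sum_{x != X} s^(n_X - n_x))` and
#' `P(X | A != X) = 1 / (1 + s^(n_X - n_A)/a + sum_{x not in {X,A}} s^(n_X - n_x))`.
#'
#' `s = 1` makes neighbor counts irrelevant; `s < 1` means the neighborhood
#' outweighs the agent's own opinion. `a = 1` makes the current state
#' irrelevant; `a < 1` is inertia (stay probability tends to 1 as `a -> 0`).
#'
#' @param counts Named numeric vector of neighbor counts per color, e.g.
#'   `c(R = 2, B = 1, Y = 0)`. Names define the alphabet.
#' @param s Social-weight parameter, `> 0`.
#' @param a Prior-odds parameter, `> 0`.
#' @param current The agent's current color (an element of `names(counts)`).
#' @return Named probability vector over the alphabet, summing to 1.
#' @examples
#' bayes_posterior_uniform(c(R = 4, B = 0, Y = 0), s = 0.5)  # 8/9 for R
#' bayes_posterior(c(R = 1, B = 1, Y = 1), current = "R", s = 0.57, a = 0.19)
#' @export
bayes_posterior_uniform <- function(counts, s) {
  check_counts(counts)
  if (!is.numeric(s) || length(s) != 1 || s <= 0) stop_("s must be a positive number")
  w <- s^(-counts)
  w / sum(w)
}

#' @rdname bayes_posterior_uniform
#' @export
bayes_posterior <- function(counts, current, s, a) {
  check_counts(counts)
  if (!is.numeric(s) || length(s) != 1 || s <= 0) stop_("s must be a positive number")
  if (!is.numeric(a) || length(a) != 1 || a <= 0) stop_("a must be a positive number")
  if (!current %in% names(counts)) stop_("current color '", current, "' not in alphabet")
  w <- s^(-counts)
  w[current] <- w[current] / a
  w / sum(w)
}

check_counts <- function(counts) {
  if (is.null(names(counts)) || any(names(counts) == "")) {
    stop_("counts must be a named vector (names are the color alphabet)")
  }
  if (any(counts < 0)) stop_("neighbor counts must be >= 0")
  invisible(counts)
}

#' Bundle of Bayesian model parameters
#'
#' @param s Social-weight parameter (`s = C'/C0`), `> 0`.
#' @param a Prior-odds parameter, `> 0`.
#' @return Object of class `bayes_params`.
#' @export
bayes_params <- function(s, a = 1) {
  if (!is.numeric(s) || length(s) != 1 || is.na(s) || s <= 0) stop_("s must be > 0")
  if (!is.numeric(a) || length(a) != 1 || is.na(a) || a <= 0) stop_("a must be > 0")
  structure(list(s = as.numeric(s), a = as.numeric(a)), class = "bayes_params")
}

#' @export
print.bayes_params <- function(x, ...) {
  cat(sprintf("<bayes_params> s = %g, a = %g\n", x$s, x$a))
  invisible(x)
}
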