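# Fitting the Bayesian aggregation model to empirical transition tables.
#
# The model predicts the probability of each decision given the full
# neighbor configuration (n_R, n_B, n_Y) and the prior color, while the
# empirical curves are marginals over one axis (n_X). Model values for a
# marginal cell are therefore computed as weighted averages of the exact
# posterior over the observed full configurations mapping to that cell,
# with weights given by the empirical configuration frequencies stored in
# the transition table.

# Reduced representation: every posterior value needed is of the form
#   p = 1 / (1 + c1(a) * s^d1 + c2(a) * s^d2)
# with exponent differences d and a-dependent coefficients; cells collapse
# to a small set of (d1, d2) tuples with pooled weights.

to_color_tuples <- function(cw, alphabet, k) {
  out <- vector("list", length(alphabet))
  names(out) <- alphabet
  for (X in alphabet) {
    others <- setdiff(alphabet, X)
    nX <- cw[[paste0("n_", X)]]
    d1 <- nX - cw[[paste0("n_", others[1])]]
    d2 <- nX - cw[[paste0("n_", others[2])]]
    out[[X]] <- lapply(0:k, function(n) {
      sel <- nX == n
      if (!any(sel)) return(NULL)
      stats::aggregate(w ~ d1 + d2,
                       data = data.frame(d1 = d1[sel], d2 = d2[sel],
                                         w = cw$count[sel]),
                       FUN = sum)
    })
  }
  out
}

stay_switch_tuples <- function(cw, alphabet, k) {
  stay <- vector("list", k + 1)
  sw <- vector("list", k + 1)
  for (r in seq_len(nrow(cw))) {
    A <- cw$from[r]
    w <- cw$count[r]
    nn <- vapply(alphabet, function(m) cw[[paste0("n_", m)]][r], numeric(1))
    others <- setdiff(alphabet, A)
    # stay cell at n = n_A: P(A|A) = 1/(1 + a*(s^d1 + s^d2))
    n <- nn[[A]]
    stay[[n + 1]] <- rbind(stay[[n + 1]],
                           c(d1 = n - nn[[others[1]]], d2 = n - nn[[others[2]]], w = w))
    # switch cells at n = n_X for X != A:
    # P(X|A) = 1/(1 + s^dA / a + s^dO), dA = n_X - n_A, dO = n_X - n_other
    for (X in others) {
      o <- setdiff(alphabet, c(A, X))
      nX <- nn[[X]]
      sw[[nX + 1]] <- rbind(sw[[nX + 1]],
                            c(d1 = nX - nn[[A]], d2 = nX - nn[[o]], w = w))
    }
  }
  pool <- function(m) {
    if (is.null(m)) return(NULL)
    stats::aggregate(w ~ d1 + d2, data = as.data.frame(m), FUN = sum)
  }
  list(stay = lapply(stay, pool), switch = lapply(sw, pool))
}

# Prediction matrices over a parameter grid. For one-parameter (uniform
# prior) cells, a is absent and the result is a vector over s_grid; for
# stay/switch cells the result is an s x a matrix.
pred_uniform <- function(tuples, s_grid) {
  if (is.null(tuples)) return(rep(NA_real_, length(s_grid)))
  acc <- 0
  for (r in seq_len(nrow(tuples))) {
    acc <- acc + tuples$w[r] / (1 + s_grid^tuples$d1[r] + s_grid^tuples$d2[r])
  }
  acc / sum(tuples$w)
}

pred_stay <- function(tuples, s_grid, a_grid) {
  if (is.null(tuples)) return(matrix(NA_real_, length(s_grid), length(a_grid)))
  acc <- matrix(0, length(s_grid), length(a_grid))
  for (r in seq_len(nrow(tuples))) {
    base <- s_grid^tuples$d1[r] + s_grid^tuples$d2[r]
    acc <- acc + tuples$w[r] / (1 + outer(base, a_grid))
  }
  acc / sum(tuples$w)
}

pred_switch <- function(tuples, s_grid, a_grid) {
  if (is.null(tuples)) return(matrix(NA_real_, length(s_grid), length(a_grid)))
  acc <- matrix(0, length(s_grid), length(a_grid))
  for (r in seq_len(nrow(tuples))) {
    acc <- acc + tuples$w[r] /
      (1 + outer(s_grid^tuples$d1[r], 1 / a_grid) + s_grid^tuples$d2[r])
  }
  acc / sum(tuples$w)
}

#' Model-predicted transition curves
#'
#' Evaluates the Bayesian model on the marginal cells of an empirical
#' transition table, marginalizing the exact posterior over the observed
#' full neighbor configurations (weighted by their empirical frequencies).
#' With `a = NULL` the uniform-prior model is evaluated on the
#' change-to-color cells `P(X | n_X)`; with `a` given, the two-parameter
#' model is evaluated on the aggregated stay and switch cells.
#'
#' @param table A [transition_table()] (its `config_weights` supply the
#'   marginalization weights).
#' @param s Social-weight parameter.
#' @param a Prior-odds parameter, or `NULL` for the uniform-prior model.
#' @return Data frame with columns `curve`, `color`, `n`, `p_model` (cells
#'   with no observed configurations are `NA`).
#' @export
predict_empirical_curves <- function(table, s, a = NULL) {
  stopifnot(inherits(table, "transition_table"))
  k <- table$k
  if (is.null(a)) {
    tup <- to_color_tuples(table$config_weights, table$alphabet, k)
    out <- do.call(rbind, lapply(table$alphabet, function(X) {
      p <- vapply(0:k, function(n) pred_uniform(tup[[X]][[n + 1]], s)[1], numeric(1))
      data.frame(curve = "to_color", color = X, n = 0:k, p_model = p)
    }))
  } else {
    tup <- stay_switch_tuples(table$config_weights, table$alphabet, k)
    p_stay <- vapply(0:k, function(n) pred_stay(tup$stay[[n + 1]], s, a)[1, 1], numeric(1))
    p_sw <- vapply(0:k, function(n) pred_switch(tup$switch[[n + 1]], s, a)[1, 1], numeric(1))
    out <- rbind(
      data.frame(curve = "stay_agg", color = "all", n = 0:k, p_model = p_stay),
      data.frame(curve = "switch_agg", color = "all", n = 0:k, p_model = p_sw)
    )
  }
  rownames(out) <- NULL
  out
}

#' Fit the uniform-prior model by grid-search RMSE
#'
#' Scans a grid of the social-weight parameter `s` and, at each value,
#' computes the root-mean-square error between the empirical
#' change-to-color probabilities `P(X | n_X)` (per color) and the model
#' predictions marginalized over the observed neighbor configurations.
#' Cells flagged low-count or undefined are excluded. The reported optimum
#' minimizes the RMSE pooled over all eligible cells; per-color RMSE curves
#' are also returned.
#'
#' @param table A [transition_table()].
#' @param s_grid Grid of `s` values (default 0.05 to 2 in steps of 0.01).
#' @param min_count Minimum cell event count (defaults to the table's).
#' @return Object of class `fit_result` with fields `s_grid`, `rmse`
#'   (pooled curve), `rmse_by_color`, `s_opt`, `rmse_opt`, `n_cells`.
#' @export
fit_one_param <- function(table, s_grid = seq(0.05, 2, by = 0.01),
                          min_count = NULL) {
  stopifnot(inherits(table, "transition_table"))
  min_count <- min_count %||% table$min_count
  k <- table$k
  emp <- table$to_color
  emp <- emp[!is.na(emp$p) & emp$count >= min_count, ]
  if (!nrow(emp)) stop_("no eligible cells (all undefined or below min_count)")
  tup <- to_color_tuples(table$config_weights, table$alphabet, k)
  sq <- matrix(0, length(s_grid), 0)
  by_color <- list()
  for (X in table$alphabet) {
    cells_X <- emp[emp$color == X, ]
    if (!nrow(cells_X)) next
    errs <- vapply(seq_len(nrow(cells_X)), function(i) {
      (pred_uniform(tup[[X]][[cells_X$n[i] + 1]], s_grid) - cells_X$p[i])^2
    }, numeric(length(s_grid)))
    errs <- matrix(errs, nrow = length(s_grid))
    by_color[[X]] <- sqrt(rowMeans(errs))
    sq <- cbind(sq, errs)
  }
  rmse <- sqrt(rowMeans(sq))
  i <- which.min(rmse)
  structure(
    list(type = "one_param", s_grid = s_grid, rmse = rmse,
         rmse_by_color = do.call(cbind, by_color),
         s_opt = s_grid[i], rmse_opt = rmse[i], n_cells = nrow(emp)),
    class = "fit_result"
  )
}

#' Fit the two-parameter model by grid-search RMSE
#'
#' Scans a two-dimensional grid of `(s, a)` and computes the RMSE between
#' the aggregated (pooled over colors) empirical stay and switch curves and
#' the model predictions marginalized over observed configurations. Returns
#' the full RMSE surface and the minimizing pair; exact ties are broken by
#' the smallest `s`, then the smallest `a`.
#'
#' @inheritParams fit_one_param
#' @param a_grid Grid of `a` values (default 0.05 to 2 in steps of 0.01).
#' @return Object of class `fit_result` with fields `s_grid`, `a_grid`,
#'   `rmse` (matrix `s x a`), `s_opt`, `a_opt`, `rmse_opt`, `n_cells`.
#' @export
fit_two_param <- function(table, s_grid = seq(0.05, 2, by = 0.01),
                          a_grid = seq(0.05, 2, by = 0.01),
                          min_count = NULL) {
  stopifnot(inherits(table, "transition_table"))
  min_count <- min_count %||% table$min_count
  k <- table$k
  stay <- table$stay_agg; sw <- table$switch_agg
  stay <- stay[!is.na(stay$p) & stay$count >= min_count, ]
  sw <- sw[!is.na(sw$p) & sw$count >= min_count, ]
  n_cells <- nrow(stay) + nrow(sw)
  if (!n_cells) stop_("no eligible cells (all undefined or below min_count)")
  tup <- stay_switch_tuples(table$config_weights, table$alphabet, k)
  acc <- matrix(0, length(s_grid), length(a_grid))
  for (i in seq_len(nrow(stay))) {
    acc <- acc + (pred_stay(tup$stay[[stay$n[i] + 1]], s_grid, a_grid) - stay$p[i])^2
  }
  for (i in seq_len(nrow(sw))) {
    acc <- acc + (pred_switch(tup$switch[[sw$n[i] + 1]], s_grid, a_grid) - sw$p[i])^2
  }
  rmse <- sqrt(acc / n_cells)
  m <- min(rmse)
  cand <- which(rmse == m, arr.ind = TRUE)
  cand <- cand[order(cand[, 1], cand[, 2]), , drop = FALSE]
  structure(
    list(type = "two_param", s_grid = s_grid, a_grid = a_grid, rmse = rmse,
         s_opt = s_grid[cand[1, 1]], a_opt = a_grid[cand[1, 2]],
         rmse_opt = m, n_cells = n_cells),
    class = "fit_result"
  )
}

#' @export
print.fit_result <- function(x, ...) {
  if (x$type == "one_param") {
    cat(sprintf("<fit_result> uniform-prior model: s = %.2f (RMSE %.4f over %d cells)\n",
                x$s_opt, x$rmse_opt, x$n_cells))
  } else {
    cat(sprintf("<fit_result> two-parameter model: s = %.2f, a = %.2f (RMSE %.4f over %d cells)\n",
                x$s_opt, x$a_opt, x$rmse_opt, x$n_cells))
  }
  invisible(x)
}

#' Export a fit result as a long data frame of grid RMSE values
#'
#' @param x A `fit_result`.
#' @param ... Unused.
#' @return Data frame with columns `s`, `a` (constant `NA` for the
#'   one-parameter fit) and `rmse`.
#' @export
as.data.frame.fit_result <- function(x, ...) {
  if (x$type == "one_param") {
    data.frame(s = x$s_grid, a = NA_real_, rmse = x$rmse)
  } else {
    data.frame(s = rep(x$s_grid, times = length(x$a_grid)),
               a = rep(x$a_grid, each = length(x$s_grid)),
               rmse = as.vector(x$rmse))
  }
}
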