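#' Build a k-regular interaction network
#'
#' The experiment places players on simple, connected, undirected networks in
#' which every node has degree exactly `k` (the study used `k = 4`). Two
#' topologies are supported: a ring lattice (`"regular_lattice"`), where each
#' node connects to its `k/2` nearest nodes on each side, and a degree-regular
#' random graph (`"random_regular"`), sampled uniformly and resampled until
#' connected.
#'
#' @param n_nodes Number of nodes; must exceed `k`.
#' @param k Node degree (even for the ring lattice; `n_nodes * k` even for the
#'   random topology).
#' @param topology `"regular_lattice"` or `"random_regular"`.
#' @param seed Optional integer seed; the random topology is deterministic
#'   given the seed.
#' @param max_tries Resampling cap for the connected random-regular draw.
#' @return An object of class `guess_network`: a list with `n_nodes`, `k`,
#'   `topology`, and `edges` (a two-column matrix of 1-based node pairs,
#'   canonically ordered).
#' @export
make_network <- function(n_nodes, k = 4,
                         topology = c("regular_lattice", "random_regular"),
                         seed = NULL, max_tries = 1000) {
  topology <- match.arg(topology)
  if (!is_count(n_nodes) || !is_count(k)) stop_("n_nodes and k must be positive integers")
  if (n_nodes <= k) stop_("need n_nodes > k (got n_nodes = ", n_nodes, ", k = ", k, ")")
  if (topology == "regular_lattice" && k %% 2 != 0) {
    stop_("regular_lattice requires even k, got k = ", k)
  }
  if (topology == "random_regular" && (n_nodes * k) %% 2 != 0) {
    stop_("random_regular requires n_nodes * k even")
  }
  edges <- switch(topology,
    regular_lattice = ring_lattice_edges(n_nodes, k),
    random_regular = with_seed(seed, {
      for (i in seq_len(max_tries)) {
        g <- igraph::sample_k_regular(n_nodes, k)
        if (igraph::is_connected(g) && igraph::is_simple(g)) {
          break
        }
        g <- NULL
      }
      if (is.null(g)) stop_("no connected simple ", k, "-regular graph found in ",
                            max_tries, " tries")
      igraph::as_edgelist(g)
    })
  )
  edges <- canonical_edges(edges)
  structure(
    list(n_nodes = as.integer(n_nodes), k = as.integer(k),
         topology = topology, edges = edges),
    class = "guess_network"
  )
}

ring_lattice_edges <- function(n, k) {
  do.call(rbind, lapply(seq_len(k / 2), function(d) {
    i <- seq_len(n)
    cbind(i, (i + d - 1L) %% n + 1L)
  }))
}

canonical_edges <- function(edges) {
  edges <- cbind(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
  edges <- unique(edges)
  edges <- edges[order(edges[, 1], edges[, 2]), , drop = FALSE]
  storage.mode(edges) <- "integer"
  dimnames(edges) <- list(NULL, c("from", "to"))
  edges
}

#' @export
print.guess_network <- function(x, ...) {
  cat(sprintf("<guess_network> %s, %d nodes, degree %d, %d edges\n",
              x$topology, x$n_nodes, x$k, nrow(x$edges)))
  invisible(x)
}

#' Convert a guess_network to an igraph graph
#'
#' @param network A `guess_network`.
#' @return An undirected `igraph` graph on nodes `1..n_nodes`.
#' @export
as_igraph <- function(network) {
  stopifnot(inherits(network, "guess_network"))
  g <- igraph::graph_from_edgelist(network$edges, directed = FALSE)
  if (igraph::vcount(g) < network$n_nodes) {
    g <- igraph::add_vertices(g, network$n_nodes - igraph::vcount(g))
  }
  g
}

#' Adjacency list of a network
#'
#' @param network A `guess_network`.
#' @return List mapping each node to the integer vector of its neighbors.
#' @export
neighbors_of <- function(network) {
  adj <- vector("list", network$n_nodes)
  for (i in seq_len(network$n_nodes)) adj[[i]] <- integer(0)
  for (r in seq_len(nrow(network$edges))) {
    a <- network$edges[[r, 1]]; b <- network$edges[[r, 2]]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  lapply(adj, function(x) sort(unname(x)))
}

validate_network <- function(network) {
  e <- network$edges
  if (any(e[, 1] == e[, 2])) stop_("network has self-loops")
  if (anyDuplicated(e)) stop_("network has multi-edges")
  if (any(e < 1 | e > network$n_nodes)) stop_("edge endpoint outside 1..n_nodes")
  deg <- tabulate(as.vector(e), nbins = network$n_nodes)
  if (any(deg != network$k)) {
    stop_("network is not ", network$k, "-regular (degrees ",
          paste(range(deg), collapse = ".."), ")")
  }
  if (!igraph::is_connected(as_igraph(network))) stop_("network is disconnected")
  invisible(network)
}
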