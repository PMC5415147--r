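#' Undirected simple network
#'
#' Light-weight container for an undirected simple graph with integer node
#' IDs `1..n_nodes`.  It stores the edge list, the degree sequence and an
#' adjacency list, which is what the payoff engine needs for fast
#' single-node community moves.
#'
#' @param edges two-column matrix or data frame of 1-based node pairs, one
#'   row per undirected edge.
#' @param n_nodes number of nodes; defaults to the largest node ID seen.
#'   Nodes with no incident edge are allowed (isolated nodes).
#' @return an object of class `"pmneo_network"` with elements `n` (node
#'   count), `m` (edge count), `edges` (canonical m x 2 integer matrix with
#'   `edges[, 1] < edges[, 2]`), `deg` (degree vector) and `adj` (list of
#'   neighbour vectors).
#' @examples
#' net <- network(rbind(c(1, 2), c(2, 3), c(1, 3)))
#' net$deg
#' @export
network <- function(edges, n_nodes = NULL) {
  if (is.data.frame(edges)) edges <- as.matrix(edges)
  if (length(edges) == 0L) {
    edges <- matrix(integer(0), ncol = 2L)
  }
  if (!is.matrix(edges) || ncol(edges) != 2L) {
    stop("'edges' must be a two-column matrix of node pairs", call. = FALSE)
  }
  storage.mode(edges) <- "integer"
  if (anyNA(edges) || any(edges < 1L)) {
    stop("node IDs must be positive integers", call. = FALSE)
  }
  if (any(edges[, 1L] == edges[, 2L])) {
    stop("self-loops are not allowed in a simple network", call. = FALSE)
  }
  if (is.null(n_nodes)) n_nodes <- if (nrow(edges)) max(edges) else 0L
  n_nodes <- as.integer(n_nodes)
  if (nrow(edges) && max(edges) > n_nodes) {
    stop("edge refers to node ID larger than 'n_nodes'", call. = FALSE)
  }
  # canonical order (small, large) then dedupe
  flip <- edges[, 1L] > edges[, 2L]
  if (any(flip)) edges[flip, ] <- edges[flip, 2:1]
  key <- (edges[, 1L] - 1) * as.double(n_nodes) + edges[, 2L]
  dup <- duplicated(key)
  if (any(dup)) {
    warning(sum(dup), " duplicate edge(s) removed", call. = FALSE)
    edges <- edges[!dup, , drop = FALSE]
  }
  edges <- edges[order(edges[, 1L], edges[, 2L]), , drop = FALSE]
  deg <- tabulate(edges, nbins = n_nodes)
  adj <- vector("list", n_nodes)
  if (nrow(edges)) {
    ends <- c(edges[, 1L], edges[, 2L])
    nbrs <- c(edges[, 2L], edges[, 1L])
    adj <- unname(split(nbrs, factor(ends, levels = seq_len(n_nodes))))
  } else if (n_nodes > 0L) {
    adj <- rep(list(integer(0)), n_nodes)
  }
  structure(
    list(n = n_nodes, m = nrow(edges), edges = edges, deg = deg, adj = adj),
    class = "pmneo_network"
  )
}

#' @export
print.pmneo_network <- function(x, ...) {
  cat("Undirected simple network:", x$n, "nodes,", x$m, "edges\n")
  invisible(x)
}

#' Coerce between `pmneo_network` and igraph graphs
#'
#' @param x a `pmneo_network`, or for [as_network()] an `igraph` graph or
#'   edge matrix/data frame.
#' @param ... unused.
#' @return [as_igraph()] returns an undirected `igraph` graph;
#'   [as_network()] returns a `pmneo_network`.
#' @export
as_igraph <- function(x, ...) {
  stopifnot(inherits(x, "pmneo_network"))
  g <- igraph::make_empty_graph(n = x$n, directed = FALSE)
  igraph::add_edges(g, t(x$edges))
}

#' @rdname as_igraph
#' @export
as_network <- function(x, ...) {
  if (inherits(x, "pmneo_network")) return(x)
  if (inherits(x, "igraph")) {
    if (igraph::is_directed(x)) x <- igraph::as_undirected(x, mode = "collapse")
    x <- igraph::simplify(x)
    return(network(igraph::as_edgelist(x, names = FALSE),
                   n_nodes = igraph::vcount(x)))
  }
  network(x, ...)
}

#' Seven-node demonstration network
#'
#' A triangle (nodes 1-3) attached to a near-clique on nodes 4-7 through the
#' bridge edge 3-4.  Its two natural communities are \{1,2,3\} and
#' \{4,5,6,7\}, making it a convenient hand-checkable input for the
#' community game: all fitness and payoff values are small rationals.
#' The same graph ships as a plain-text edge list in
#' `system.file("extdata", "demo7.edges", package = "pmneo")`.
#'
#' @return a `pmneo_network` with 7 nodes and 10 edges.
#' @examples
#' community_fitness(1:3, demo_network7())  # 6/7
#' @export
demo_network7 <- function() {
  network(rbind(
    c(1L, 2L), c(1L, 3L), c(2L, 3L), c(3L, 4L), c(4L, 5L),
    c(4L, 6L), c(4L, 7L), c(5L, 6L), c(5L, 7L), c(6L, 7L)
  ))
}
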