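#' Read and write networks
#'
#' Networks are exchanged as whitespace-separated edge lists with 1-based
#' node IDs and `#` comments (the format used by most benchmark generators),
#' or as GML / Pajek `.net` files, which are parsed by igraph.  Reading and
#' writing round-trips the edge set exactly; duplicate edges (including
#' reversed duplicates) are collapsed with a warning.
#'
#' @param path file path.
#' @param format `"edgelist"`, `"gml"`, `"pajek"`, or `"auto"` to guess from
#'   the file extension (`.gml` / `.net`, anything else is an edge list).
#' @param n_nodes optional node count for edge lists whose largest node ID
#'   underestimates the network size.
#' @return [read_network()] returns a `pmneo_network`.
#' @export
read_network <- function(path, format = c("auto", "edgelist", "gml", "pajek"),
                         n_nodes = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, gml = "gml", net = "pajek", "edgelist")
  }
  if (format %in% c("gml", "pajek")) {
    g <- igraph::read_graph(path, format = format)
    return(as_network(g))
  }
  lines <- readLines(path, warn = FALSE)
  stripped <- sub("#.*$", "", lines)
  keep <- which(nzchar(trimws(stripped)))
  pairs <- matrix(0L, nrow = length(keep), ncol = 2L)
  for (r in seq_along(keep)) {
    ln <- keep[r]
    tok <- strsplit(trimws(stripped[ln]), "[[:space:]]+")[[1L]]
    ids <- suppressWarnings(as.integer(tok))
    if (length(ids) < 2L || anyNA(ids[1:2])) {
      stop(sprintf("%s: cannot parse edge on line %d: '%s'",
                   path, ln, lines[ln]), call. = FALSE)
    }
    pairs[r, ] <- ids[1:2]
  }
  network(pairs, n_nodes = n_nodes)
}

#' @rdname read_network
#' @param net a `pmneo_network`.
#' @export
write_network <- function(net, path,
                          format = c("auto", "edgelist", "gml", "pajek")) {
  stopifnot(inherits(net, "pmneo_network"))
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, gml = "gml", net = "pajek", "edgelist")
  }
  if (format %in% c("gml", "pajek")) {
    igraph::write_graph(as_igraph(net), path, format = format)
  } else {
    writeLines(paste(net$edges[, 1L], net$edges[, 2L]), path)
  }
  invisible(path)
}

#' Read and write partitions
#'
#' A partition file has two whitespace-separated columns, `node community`,
#' with 1-based node IDs; `#` starts a comment.  Nodes may appear in any
#' order but each node must appear exactly once.
#'
#' @param path file path.
#' @param n_nodes optional expected number of nodes; the labels are checked
#'   against it.
#' @return [read_partition()] returns an integer label vector of length
#'   `n_nodes`.
#' @export
read_partition <- function(path, n_nodes = NULL) {
  tab <- utils::read.table(path, comment.char = "#",
                           col.names = c("node", "community"))
  node <- as.integer(tab$node)
  lab <- as.integer(tab$community)
  if (anyNA(node) || anyNA(lab)) {
    stop(path, ": partition file must contain integer node/community pairs",
         call. = FALSE)
  }
  if (is.null(n_nodes)) n_nodes <- max(node)
  if (anyDuplicated(node) || !setequal(node, seq_len(n_nodes))) {
    stop(path, ": each node 1..n must appear exactly once", call. = FALSE)
  }
  out <- integer(n_nodes)
  out[node] <- lab
  out
}

#' @rdname read_partition
#' @param labels integer community label vector (index = node ID).
#' @export
write_partition <- function(labels, path) {
  writeLines(paste(seq_along(labels), as.integer(labels)), path)
  invisible(path)
}
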