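#' Simple undirected network container
#'
#' A `module_network` is a labelled simple undirected unweighted graph:
#' node labels plus an adjacency list (1-based integer neighbour indices).
#' All module-extraction algebra in this package operates on the implied
#' binary adjacency matrix, which is symmetric with a zero diagonal.
#'
#' @param edges two-column character matrix or data.frame of edges
#'   (one edge per row); duplicate edges and reversed duplicates are
#'   collapsed, self-loops are dropped with a warning.
#' @param nodes optional character vector of node labels; must contain
#'   every label appearing in `edges`. Extra labels become isolated
#'   nodes. Defaults to labels in first-appearance order over `edges`.
#'
#' @return An object of class `module_network` with elements
#'   `nodes` (character), `adj` (list of integer neighbour indices) and
#'   `n_edges` (integer).
#' @export
module_network <- function(edges, nodes = NULL) {
  if (is.data.frame(edges)) edges <- as.matrix(edges)
  if (length(edges) == 0L) {
    em <- matrix(character(), ncol = 2L)
  } else {
    if (!is.matrix(edges) || ncol(edges) != 2L)
      stop("'edges' must be a two-column matrix of node labels")
    em <- matrix(as.character(edges), ncol = 2L)
  }
  if (is.null(nodes)) {
    nodes <- unique(as.vector(t(em)))
  } else {
    nodes <- as.character(nodes)
    missing <- setdiff(unique(as.vector(em)), nodes)
    if (length(missing))
      stop("edge labels not in 'nodes': ", paste(missing, collapse = ", "))
  }
  if (anyDuplicated(nodes)) stop("node labels must be unique")
  n <- length(nodes)
  i <- match(em[, 1L], nodes)
  j <- match(em[, 2L], nodes)
  loops <- i == j
  if (any(loops)) {
    warning(sum(loops), " self-loop(s) dropped")
    i <- i[!loops]; j <- j[!loops]
  }
  lo <- pmin(i, j); hi <- pmax(i, j)
  keep <- !duplicated(cbind(lo, hi))
  lo <- lo[keep]; hi <- hi[keep]
  adj <- rep(list(integer(0)), n)
  if (length(lo)) {
    adj <- split(c(hi, lo), factor(c(lo, hi), levels = seq_len(n)))
    adj <- lapply(adj, function(x) sort(as.integer(x)))
    names(adj) <- NULL
  }
  structure(
    list(nodes = nodes, adj = adj, n_edges = length(lo)),
    class = "module_network"
  )
}

#' @export
print.module_network <- function(x, ...) {
  cat("module_network: ", length(x$nodes), " nodes, ", x$n_edges,
      " edges\n", sep = "")
  invisible(x)
}

#' Number of nodes in a network
#' @param net a `module_network`
#' @return integer node count
#' @export
network_size <- function(net) {
  stopifnot(inherits(net, "module_network"))
  length(net$nodes)
}

#' Node degrees
#' @param net a `module_network`
#' @return named integer vector of degrees
#' @export
network_degrees <- function(net) {
  stopifnot(inherits(net, "module_network"))
  stats::setNames(lengths(net$adj), net$nodes)
}

#' Edge list of a network
#' @param net a `module_network`
#' @return two-column character matrix, one row per edge, lower index first
#' @export
network_edges <- function(net) {
  stopifnot(inherits(net, "module_network"))
  n <- length(net$nodes)
  from <- rep.int(seq_len(n), lengths(net$adj))
  to <- unlist(net$adj, use.names = FALSE)
  keep <- from < to
  cbind(net$nodes[from[keep]], net$nodes[to[keep]])
}

#' Delete nodes from a network
#'
#' Removes the named nodes together with all incident edges; used by the
#' sequential extraction loop, which deletes each extracted module before
#' searching for the next one.
#'
#' @param net a `module_network`
#' @param drop character vector of node labels to remove
#' @return the reduced `module_network`
#' @export
network_delete_nodes <- function(net, drop) {
  stopifnot(inherits(net, "module_network"))
  idx <- match(drop, net$nodes)
  if (anyNA(idx)) stop("unknown node label(s): ",
                       paste(drop[is.na(idx)], collapse = ", "))
  keep <- setdiff(seq_along(net$nodes), idx)
  remap <- integer(length(net$nodes))
  remap[keep] <- seq_along(keep)
  adj <- lapply(net$adj[keep], function(nb) remap[nb[!(nb %in% idx)]])
  structure(
    list(nodes = net$nodes[keep], adj = adj,
         n_edges = sum(lengths(adj)) %/% 2L),
    class = "module_network"
  )
}

#' Convert to an igraph object
#' @param net a `module_network`
#' @return an [igraph::graph] with vertex attribute `name`
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "module_network"))
  igraph::graph_from_data_frame(
    as.data.frame(network_edges(net), stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = net$nodes, stringsAsFactors = FALSE)
  )
}

#' Read an edge list file
#'
#' Reads a two-column whitespace/tab separated edge list into a
#' [module_network()]. A header line is tolerated when `header = TRUE`.
#' Duplicate and reversed-duplicate edges are collapsed; self-loops are
#' dropped with a warning. Node order is first-appearance order.
#'
#' @param path file path
#' @param header logical; does the first line carry column names?
#' @return a `module_network`
#' @export
read_edge_list <- function(path, header = FALSE) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (header && length(lines)) lines <- lines[-1L]
  if (!length(lines)) stop("empty edge list file: ", path)
  parts <- strsplit(trimws(lines), "[ \t]+")
  bad <- which(lengths(parts) != 2L)
  if (length(bad))
    stop("malformed edge list line ", bad[1L] + as.integer(header),
         " in ", path, ": expected 2 columns, found ",
         length(parts[[bad[1L]]]))
  em <- matrix(unlist(parts), ncol = 2L, byrow = TRUE)
  module_network(em)
}

#' Write an edge list file
#' @param net a `module_network`
#' @param path file path; tab-separated, no header
#' @return `path`, invisibly
#' @export
write_edge_list <- function(net, path) {
  em <- network_edges(net)
  utils::write.table(em, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
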