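#' Extraction configuration
#'
#' Parameters of the sample-and-seed module search. `M` is the number of
#' seeded solutions optimised in the main stage (the original authors
#' report that 50--100 solutions give satisfactory results; 100 is the
#' default). `K_sampling` is the number of gradient-probability solutions
#' in the sampling stage and defaults to `M`. Modules smaller than
#' `min_module_size` (default 3, i.e. size > 2) are not reported.
#'
#' @param M number of seeded solutions (default 100)
#' @param K_sampling sampling-stage solution count (default `M`)
#' @param min_module_size smallest reported module size (default 3)
#' @param seed optional integer; when non-`NULL`, `set.seed(seed)` is
#'   called before any random draw so runs are reproducible
#' @param max_sweeps safety bound on local-moving sweeps (default 1000)
#' @return a list of class `extraction_config`
#' @export
extraction_config <- function(M = 100L, K_sampling = M,
                              min_module_size = 3L, seed = NULL,
                              max_sweeps = 1000L) {
  stopifnot(M >= 1L, K_sampling >= 1L, min_module_size >= 1L,
            max_sweeps >= 1L)
  structure(list(M = as.integer(M), K_sampling = as.integer(K_sampling),
                 min_module_size = as.integer(min_module_size),
                 seed = seed, max_sweeps = as.integer(max_sweeps)),
            class = "extraction_config")
}

.members_to_x <- function(net, members) {
  idx <- match(members, net$nodes)
  if (anyNA(idx)) stop("unknown node label(s): ",
                       paste(members[is.na(idx)], collapse = ", "))
  x <- integer(length(net$nodes))
  x[idx] <- 1L
  x
}

#' Community-extraction criterion W
#'
#' W(C) = |C| |C~| ( O(C)/|C|^2 - B(C)/(|C||C~|) ) = |C~| O(C)/|C| - B(C),
#' where O(C) counts ordered within-module adjacent pairs (each internal
#' edge twice) and B(C) counts module-to-background edges. W is 0 by
#' convention for the empty and the full node set. Large W means a node
#' set dense inside and sparse towards the rest of the network.
#'
#' @param net a [module_network()]
#' @param members character vector of module node labels, or a 0/1
#'   membership vector of length `network_size(net)`
#' @return the criterion value (numeric scalar)
#' @export
criterion_w <- function(net, members) {
  stopifnot(inherits(net, "module_network"))
  x <- if (is.character(members)) .members_to_x(net, members)
       else {
         stopifnot(length(members) == length(net$nodes))
         as.integer(members != 0)
       }
  cpp_criterion_w(net$adj, x)
}

#' Criterion change for a single membership flip
#'
#' Evaluates W(after flipping node `v`) - W(before) from the cached
#' criterion state (|C|, O, B, d_in) in constant time, without a full
#' recomputation — the bookkeeping that makes local moving fast.
#'
#' @param net a [module_network()]
#' @param members current module (labels or 0/1 vector, as in
#'   [criterion_w()])
#' @param v node label (or index) to flip
#' @return the change in W (numeric scalar)
#' @export
delta_w <- function(net, members, v) {
  stopifnot(inherits(net, "module_network"))
  x <- if (is.character(members)) .members_to_x(net, members)
       else as.integer(members != 0)
  vi <- if (is.character(v)) match(v, net$nodes) else as.integer(v)
  if (is.na(vi) || vi < 1L || vi > length(net$nodes))
    stop("unknown node: ", v)
  cpp_delta_w(net$adj, x, vi)
}

#' Local moving to a 1-flip optimum
#'
#' Sweeps the nodes in ascending index order, flipping any membership
#' whose flip increases W, and repeats until a full sweep makes no flip.
#' The result is a local optimum under single-node flips with
#' W(out) >= W(in); re-running on its own output is a no-op.
#'
#' @param net a [module_network()]
#' @param x0 starting 0/1 membership vector (length `network_size(net)`)
#'   or character member labels
#' @param max_sweeps safety bound (default 1000); exceeded only if the
#'   incremental update is inconsistent
#' @return list with `x` (0/1 vector), `members` (labels), `W`, `sweeps`
#' @export
local_moving <- function(net, x0, max_sweeps = 1000L) {
  stopifnot(inherits(net, "module_network"))
  x <- if (is.character(x0)) .members_to_x(net, x0)
       else {
         stopifnot(length(x0) == length(net$nodes))
         as.integer(x0 != 0)
       }
  res <- cpp_local_moving(net$adj, x, as.integer(max_sweeps))
  list(x = res$x, members = net$nodes[res$x == 1L], W = res$W,
       sweeps = res$sweeps)
}

#' Sampling stage of the sample-and-seed search
#'
#' Solution k (k = 1..K) is initialised with independent per-node
#' inclusion probability p_k = 0.5 k / K — an even gradient of
#' probabilities capped at 0.5, reflecting the assumption that no
#' meaningful module covers more than half of a large network — and then
#' optimised by [local_moving()]. The per-node appearance counts f over
#' the positive-W optimised solutions form the raw material of the seed
#' PMF (zero-W optima — the empty set, or stranded isolated nodes —
#' carry no module signal and are not counted).
#'
#' @param net a [module_network()]
#' @param K number of sampling solutions
#' @param keep_solutions return the K optimised 0/1 solutions as a matrix?
#' @param max_sweeps safety bound for local moving
#' @return list with `f` (named appearance counts), `W` (criterion value
#'   of each optimised solution) and, if requested, `solutions`
#'   (K x N 0/1 matrix)
#' @export
sample_stage <- function(net, K, keep_solutions = FALSE,
                         max_sweeps = 1000L) {
  stopifnot(inherits(net, "module_network"), K >= 1L)
  res <- cpp_sample_stage(net$adj, as.integer(K), as.integer(max_sweeps),
                          isTRUE(keep_solutions))
  out <- list(f = stats::setNames(res$f, net$nodes), W = res$W)
  if (isTRUE(keep_solutions)) {
    colnames(res$solutions) <- net$nodes
    out$solutions <- res$solutions
  }
  out
}

#' Seed probabilities from sampling frequencies
#'
#' Normalises the appearance counts into a probability mass function over
#' nodes: P_i = f_i / sum_j f_j. Nodes never seen in a sampling-stage
#' optimum get seed probability exactly 0.
#'
#' @param f non-negative frequency vector (named by node)
#' @return list with `f` and `P` (both named), class `seed_profile`
#' @export
seed_probabilities <- function(f) {
  f <- as.numeric(f)
  if (any(f < 0)) stop("frequencies must be non-negative")
  tot <- sum(f)
  if (tot <= 0)
    stop("sampling stage found no module signal (all frequencies zero)")
  structure(list(f = f, P = f / tot), class = "seed_profile")
}

#' Extract the single best module
#'
#' Runs the two-stage sample-and-seed search: `K_sampling` gradient
#' solutions are optimised and their node frequencies converted into a
#' seed PMF; `M` solutions are then seeded (node i enters a seed iff a
#' uniform draw falls below P_i), each optimised by [local_moving()], and
#' the highest-W solution is returned (first found wins ties). If the
#' sampling stage finds no node with positive frequency — e.g. on an
#' edgeless network, where every local optimum is empty — the empty
#' solution with W = 0 is returned.
#'
#' @param net a [module_network()]
#' @param config an [extraction_config()]
#' @return list with `members` (labels), `x` (0/1 vector), `W`
#' @export
extract_module <- function(net, config = extraction_config()) {
  stopifnot(inherits(net, "module_network"),
            inherits(config, "extraction_config"))
  if (length(net$nodes) == 0L) stop("network is empty")
  if (!is.null(config$seed)) set.seed(config$seed)
  res <- cpp_extract_module(net$adj, config$M, config$K_sampling,
                            config$max_sweeps)
  list(members = net$nodes[res$x == 1L], x = res$x, W = res$W)
}

#' Sequential extraction of all modules
#'
#' Repeatedly extracts the best module and, when its W is positive,
#' deletes its nodes and incident edges from the network before searching
#' again; extraction stops when the best attainable W is no longer
#' positive or fewer than `min_module_size` nodes remain. Only modules
#' with at least `min_module_size` members (default 3, i.e. size > 2) are
#' reported; each carries its W at extraction and a connectivity
#' diagnostic — a disconnected extracted module is reported with
#' `connected = FALSE` and a warning, never silently split.
#'
#' @param net a [module_network()]
#' @param config an [extraction_config()]
#' @return a [module_set()] of the reported modules, in extraction order
#' @export
extract_all <- function(net, config = extraction_config()) {
  stopifnot(inherits(net, "module_network"),
            inherits(config, "extraction_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  cfg <- config
  cfg$seed <- NULL  # single RNG stream across the whole sequence
  cur <- net
  mods <- list(); Ws <- numeric(); conn <- logical(); ord <- integer()
  k <- 0L
  while (length(cur$nodes) >= config$min_module_size) {
    best <- extract_module(cur, cfg)
    if (best$W <= 0 || length(best$members) == 0L) break
    k <- k + 1L
    if (length(best$members) >= config$min_module_size) {
      is_conn <- .is_connected_subgraph(cur, best$members)
      if (!is_conn)
        warning("module extracted at step ", k, " is disconnected")
      mods[[length(mods) + 1L]] <- best$members
      Ws <- c(Ws, best$W)
      conn <- c(conn, is_conn)
      ord <- c(ord, k)
    }
    cur <- network_delete_nodes(cur, best$members)
  }
  ms <- module_set(mods, W = Ws, connected = conn,
                   provenance = sprintf("extract_all(M=%d, K=%d, min_size=%d)",
                                        config$M, config$K_sampling,
                                        config$min_module_size))
  ms$extraction_order <- ord
  ms
}

.is_connected_subgraph <- function(net, members) {
  idx <- match(members, net$nodes)
  if (length(idx) <= 1L) return(TRUE)
  g <- as_igraph(net)
  sg <- igraph::induced_subgraph(g, members)
  igraph::is_connected(sg)
}
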