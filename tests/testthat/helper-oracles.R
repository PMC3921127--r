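# Pure-R oracles and fixture builders, independent of the C++ search path.

# dense adjacency matrix of a module_network
adj_matrix <- function(net) {
  n <- length(net$nodes)
  A <- matrix(0L, n, n, dimnames = list(net$nodes, net$nodes))
  for (v in seq_len(n)) A[v, net$adj[[v]]] <- 1L
  A
}

# full criterion recomputation from the membership vector
w_recompute <- function(A, x) {
  n <- nrow(A)
  s <- sum(x)
  if (s == 0) return(0)
  O <- as.numeric(t(x) %*% A %*% x)
  B <- sum(rowSums(A)[x == 1]) - O
  (n - s) * O / s - B
}

# exhaustive maximum of W over all 2^n subsets (n <= ~16)
exhaustive_max_w <- function(A) {
  n <- nrow(A)
  masks <- 0:(2^n - 1)
  Mx <- matrix(0, length(masks), n)
  for (b in seq_len(n)) Mx[, b] <- bitwAnd(masks, bitwShiftL(1L, b - 1L)) > 0
  O <- rowSums((Mx %*% A) * Mx)
  degsum <- as.numeric(Mx %*% rowSums(A))
  B <- degsum - O
  s <- rowSums(Mx)
  W <- ifelse(s == 0, 0, (n - s) * O / s - B)
  max(W)
}

# brute-force maximum-similarity assignment (rows <= cols <= 7)
brute_force_assignment <- function(S) {
  nr <- nrow(S); nc <- ncol(S)
  stopifnot(nr <= nc)
  perms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
    out
  }
  best <- -Inf; best_cols <- NULL
  for (cols in utils::combn(nc, nr, simplify = FALSE)) {
    for (p in perms(cols)) {
      tot <- sum(S[cbind(seq_len(nr), p)])
      if (tot > best) { best <- tot; best_cols <- p }
    }
  }
  list(total = best, cols = best_cols)
}

# fixtures -------------------------------------------------------------

k_clique_edges <- function(labels) t(utils::combn(labels, 2))

triangle_isolate_net <- function() {
  module_network(cbind(c("1", "1", "2"), c("2", "3", "3")),
                 nodes = c("1", "2", "3", "4"))
}

two_k4_net <- function() {
  a <- paste0("a", 1:4); b <- paste0("b", 1:4)
  module_network(rbind(k_clique_edges(a), k_clique_edges(b)),
                 nodes = c(a, b, "i1", "i2"))
}

er_network <- function(n, p, seed = NULL) {
  planted_module_network(n, integer(0), p_in = p, p_out = p,
                         seed = seed)$network
}

random_membership <- function(n, p = 0.5) as.integer(runif(n) < p)
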