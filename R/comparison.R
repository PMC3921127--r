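#' Jaccard index of two sets
#'
#' |a intersect b| / |a union b|, with 0 by convention when both sets are
#' empty.
#'
#' @param a,b vectors treated as sets
#' @return numeric in [0, 1]
#' @export
jaccard <- function(a, b) {
  a <- unique(a); b <- unique(b)
  u <- length(union(a, b))
  if (u == 0L) return(0)
  length(intersect(a, b)) / u
}

#' Project a module set onto a gene universe
#'
#' Replaces every module by its intersection with `universe`; modules
#' that lose all members are retained as empty sets (downstream size
#' filters deal with them). Used when comparing module sets discovered
#' on different microarray platforms, whose gene universes differ.
#'
#' @param ms a [module_set()]
#' @param universe character vector of gene labels
#' @return the projected `module_set`
#' @export
project_modules <- function(ms, universe) {
  stopifnot(inherits(ms, "module_set"))
  ms$modules <- lapply(ms$modules, function(m) intersect(m, universe))
  ms
}

.max_jaccard_scores <- function(ref_mods, val_mods, min_size) {
  eligible <- lengths(ref_mods) > min_size
  if (!any(eligible))
    stop("no reference module larger than ", min_size,
         " survives the size filter")
  scores <- vapply(ref_mods[eligible], function(m) {
    if (length(val_mods) == 0L) return(0)
    max(vapply(val_mods, function(v) jaccard(m, v), numeric(1)))
  }, numeric(1))
  list(scores = scores, mean = mean(scores))
}

#' Module reproducibility across independent datasets
#'
#' Projects both module sets onto the intersection of the two gene
#' universes, then scores every projected reference module with more
#' than `min_size` members by its maximum Jaccard index over the
#' projected validation modules (its best-matching counterpart).
#'
#' @param ref reference [module_set()]
#' @param val validation [module_set()]
#' @param ref_universe,val_universe gene universes of the two source
#'   networks
#' @param min_size strict size filter: only reference modules with size
#'   > `min_size` are scored (default 5)
#' @return list with `scores` (named per reference module) and `mean`
#' @export
reproducibility_scores <- function(ref, val, ref_universe, val_universe,
                                   min_size = 5L) {
  stopifnot(inherits(ref, "module_set"), inherits(val, "module_set"),
            length(ref_universe) > 0L, length(val_universe) > 0L)
  common <- intersect(ref_universe, val_universe)
  refp <- project_modules(ref, common)
  valp <- project_modules(val, common)
  .max_jaccard_scores(refp$modules, valp$modules, min_size)
}

#' Module conservation under edge noise
#'
#' Same best-match Jaccard contract as [reproducibility_scores()] but on
#' a shared node universe (no projection): each reference module larger
#' than `min_size` is scored against the modules extracted from a noisy
#' (re-thresholded) version of the same network.
#'
#' @param ref reference [module_set()]
#' @param noisy [module_set()] from the noisy network
#' @param min_size strict size filter (default 5)
#' @return list with `scores` and `mean`
#' @export
conservation_scores <- function(ref, noisy, min_size = 5L) {
  stopifnot(inherits(ref, "module_set"), inherits(noisy, "module_set"))
  .max_jaccard_scores(ref$modules, noisy$modules, min_size)
}

#' Pairwise Jaccard similarity matrix of two module sets
#'
#' Built-in alternative to an externally computed (e.g. GO semantic)
#' similarity matrix for [match_modules()].
#'
#' @param ms1,ms2 [module_set()]s
#' @return numeric matrix, rows = `ms1` modules, columns = `ms2` modules
#' @export
jaccard_similarity_matrix <- function(ms1, ms2) {
  stopifnot(inherits(ms1, "module_set"), inherits(ms2, "module_set"))
  S <- outer(seq_along(ms1$modules), seq_along(ms2$modules),
             Vectorize(function(i, j)
               jaccard(ms1$modules[[i]], ms2$modules[[j]])))
  dimnames(S) <- list(names(ms1$modules), names(ms2$modules))
  S
}

#' Read a similarity matrix TSV
#'
#' Square or rectangular numeric matrix with row and column module ids
#' (first column = row ids, header = column ids); e.g. a precomputed GO
#' semantic similarity matrix.
#'
#' @param path file path
#' @return numeric matrix with dimnames
#' @export
read_similarity_matrix <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  S <- as.matrix(df[, -1L, drop = FALSE])
  rownames(S) <- as.character(df[[1L]])
  storage.mode(S) <- "double"
  if (any(!is.finite(S))) stop("similarity matrix has non-finite entries")
  S
}

# Jonker-Volgenant style shortest augmenting path solver for the square
# linear assignment problem (minimise cost).  O(n^3).  Returns the
# column assigned to each row.
.lap_min <- function(cost) {
  n <- nrow(cost)
  stopifnot(ncol(cost) == n)
  u <- numeric(n + 1L); v <- numeric(n + 1L)
  p <- integer(n + 1L)           # p[j]: row assigned to column j (0 = none)
  way <- integer(n + 1L)
  INF <- .Machine$double.xmax / 4
  for (i in seq_len(n)) {
    p[1L] <- i
    j0 <- 1L
    minv <- rep(INF, n + 1L)
    used <- rep(FALSE, n + 1L)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]; delta <- INF; j1 <- 0L
      for (j in 2L:(n + 1L)) {
        if (!used[j]) {
          cur <- cost[i0, j - 1L] - u[i0 + 0L] - v[j]
          if (cur < minv[j]) { minv[j] <- cur; way[j] <- j0 }
          if (minv[j] < delta) { delta <- minv[j]; j1 <- j }
        }
      }
      for (j in seq_len(n + 1L)) {
        if (used[j]) {
          u[p[j]] <- u[p[j]] + delta
          v[j] <- v[j] - delta
        } else {
          minv[j] <- minv[j] - delta
        }
      }
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == 1L) break
    }
  }
  assign_row <- integer(n)
  for (j in 2L:(n + 1L)) assign_row[p[j]] <- j - 1L
  assign_row
}

#' Optimal one-to-one module matching (Hungarian assignment)
#'
#' Finds the one-to-one assignment of row modules to column modules that
#' maximises total similarity. Rectangular matrices are padded internally
#' with zero-similarity dummy entries; modules matched to a dummy are
#' reported as unmatched.
#'
#' @param S numeric similarity matrix (rows x columns, finite entries)
#' @return list with `pairs` (data.frame `row`, `col`, `similarity` for
#'   real matches), `total` (their similarity sum), `unmatched_rows`,
#'   `unmatched_cols`
#' @export
match_modules <- function(S) {
  stopifnot(is.matrix(S), all(is.finite(S)))
  nr <- nrow(S); nc <- ncol(S)
  n <- max(nr, nc)
  Sp <- matrix(0, n, n)
  Sp[seq_len(nr), seq_len(nc)] <- S
  cost <- max(Sp) - Sp
  a <- .lap_min(cost)
  rows <- seq_len(nr)
  cols <- a[rows]
  real <- cols <= nc
  rn <- rownames(S); cn <- colnames(S)
  pairs <- data.frame(
    row = if (is.null(rn)) rows[real] else rn[rows[real]],
    col = if (is.null(cn)) cols[real] else cn[cols[real]],
    similarity = S[cbind(rows[real], cols[real])],
    stringsAsFactors = FALSE
  )
  list(pairs = pairs, total = sum(pairs$similarity),
       unmatched_rows = if (is.null(rn)) rows[!real] else rn[rows[!real]],
       unmatched_cols = {
         um <- setdiff(seq_len(nc), cols[real])
         if (is.null(cn)) um else cn[um]
       })
}

#' Common modules of matched pairs
#'
#' Intersects the member sets of each matched module pair and keeps
#' intersections with at least `min_size` genes (pairs sharing fewer
#' genes are discarded as likely artifacts of noise).
#'
#' @param ms1,ms2 the two [module_set()]s that were matched
#' @param pairs data.frame with columns `row`, `col` as returned by
#'   [match_modules()] (module ids into `ms1` and `ms2`)
#' @param min_size minimum intersection size kept (default 5)
#' @return a [module_set()] of the common modules
#' @export
common_modules <- function(ms1, ms2, pairs, min_size = 5L) {
  stopifnot(inherits(ms1, "module_set"), inherits(ms2, "module_set"),
            is.data.frame(pairs), all(c("row", "col") %in% names(pairs)))
  inter <- lapply(seq_len(nrow(pairs)), function(k) {
    m1 <- ms1$modules[[as.character(pairs$row[k])]]
    m2 <- ms2$modules[[as.character(pairs$col[k])]]
    if (is.null(m1) || is.null(m2)) stop("pair refers to unknown module id")
    intersect(m1, m2)
  })
  names(inter) <- paste0(pairs$row, "+", pairs$col)
  keep <- lengths(inter) >= min_size
  module_set(inter[keep], provenance = "common_modules")
}
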