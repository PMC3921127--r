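#' Phenotype table with ordered groups
#'
#' Maps each sample to a group drawn from an ordered list of labels
#' (e.g. normal < grade II < GBM), the ordering the trend test uses.
#'
#' @param sample_id character vector of sample labels
#' @param group character vector, same length, of group labels
#' @param levels ordered group labels from lowest to highest; default the
#'   order of first appearance in `group`
#' @return data.frame of class `phenotype_table` with columns
#'   `sample_id`, `group` (ordered factor)
#' @export
phenotype_table <- function(sample_id, group, levels = unique(group)) {
  stopifnot(length(sample_id) == length(group))
  if (anyDuplicated(sample_id)) stop("duplicate sample ids")
  if (!all(group %in% levels))
    stop("group label(s) missing from 'levels': ",
         paste(setdiff(group, levels), collapse = ", "))
  structure(
    data.frame(sample_id = as.character(sample_id),
               group = factor(group, levels = levels, ordered = TRUE),
               stringsAsFactors = FALSE),
    class = c("phenotype_table", "data.frame")
  )
}

#' Read a phenotype table TSV
#'
#' Two tab-separated columns `sample_id`, `group`; the group ordering is
#' either supplied or taken from first appearance.
#'
#' @param path file path
#' @param levels optional ordered group labels
#' @return a [phenotype_table()]
#' @export
read_phenotype_table <- function(path, levels = NULL) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  if (!all(c("sample_id", "group") %in% names(df)))
    stop("phenotype file needs 'sample_id' and 'group' columns")
  if (is.null(levels)) levels <- unique(df$group)
  phenotype_table(df$sample_id, df$group, levels)
}

#' Module expression signature
#'
#' Per-sample arithmetic mean of the expression values of the module's
#' member genes — the module's activity profile across the cohort.
#'
#' @param X numeric expression matrix (genes x samples) with gene
#'   rownames
#' @param module character vector of member gene labels; all must be
#'   rows of `X`
#' @return named numeric vector, one value per sample
#' @export
module_signature <- function(X, module) {
  stopifnot(is.matrix(X), !is.null(rownames(X)))
  missing <- setdiff(module, rownames(X))
  if (length(missing))
    stop("module gene(s) absent from the expression matrix: ",
         paste(missing, collapse = ", "))
  colMeans(X[module, , drop = FALSE])
}

#' Log fold change of a signature between two groups
#'
#' On log2-scale expression the fold change of the average module
#' expression in `group` relative to `reference` is the difference of
#' group means of the signature.
#'
#' @param signature named per-sample vector (names = sample ids)
#' @param pheno a [phenotype_table()]
#' @param group,reference group labels to compare
#' @return numeric scalar: mean(signature in group) - mean(in reference)
#' @export
log_fold_change <- function(signature, pheno, group, reference) {
  stopifnot(inherits(pheno, "phenotype_table"))
  sel <- function(g) {
    ids <- pheno$sample_id[pheno$group == g]
    if (!length(ids)) stop("empty group: ", g)
    v <- signature[ids]
    if (anyNA(v)) stop("signature missing sample(s) of group ", g)
    v
  }
  mean(sel(group)) - mean(sel(reference))
}

.jt_statistic <- function(values, g) {
  lev <- levels(g)
  jt <- 0
  for (a in seq_along(lev)[-length(lev)]) {
    xa <- values[g == lev[a]]
    for (b in (a + 1L):length(lev)) {
      xb <- values[g == lev[b]]
      cmp <- outer(xa, xb, "<")
      tie <- outer(xa, xb, "==")
      jt <- jt + sum(cmp) + 0.5 * sum(tie)
    }
  }
  jt
}

# tie-corrected null moments of the JT statistic (Hollander & Wolfe)
.jt_moments <- function(n_g, tie_sizes) {
  N <- sum(n_g)
  mu <- (N^2 - sum(n_g^2)) / 4
  t1 <- N * (N - 1) * (2 * N + 5) -
    sum(n_g * (n_g - 1) * (2 * n_g + 5)) -
    sum(tie_sizes * (tie_sizes - 1) * (2 * tie_sizes + 5))
  t2 <- sum(n_g * (n_g - 1) * (n_g - 2)) *
    sum(tie_sizes * (tie_sizes - 1) * (tie_sizes - 2))
  t3 <- sum(n_g * (n_g - 1)) * sum(tie_sizes * (tie_sizes - 1))
  v <- t1 / 72 +
    t2 / (36 * N * (N - 1) * (N - 2)) +
    t3 / (8 * N * (N - 1))
  list(mean = mu, var = v)
}

# all assignments of N items into groups of sizes n_g (multiset
# permutations of group labels), as a matrix of label indices
.group_assignments <- function(n_g) {
  N <- sum(n_g)
  rec <- function(slots, sizes) {
    if (length(sizes) == 1L)
      return(matrix(slots, nrow = 1L))
    picks <- utils::combn(slots, sizes[1L])
    out <- list()
    for (c_i in seq_len(ncol(picks))) {
      rest <- rec(setdiff(slots, picks[, c_i]), sizes[-1L])
      blk <- cbind(matrix(rep(picks[, c_i], nrow(rest)),
                          nrow = nrow(rest), byrow = TRUE), rest)
      out[[length(out) + 1L]] <- blk
    }
    do.call(rbind, out)
  }
  rec(seq_len(N), n_g)
}

#' Jonckheere-Terpstra trend test across ordered groups
#'
#' Tests for a monotone trend of `values` across the ordered groups of
#' `pheno`. The statistic sums, over ordered group pairs (g < h), the
#' number of observation pairs with x_g < x_h plus half the ties. The
#' two-sided p-value is 2 min(lower tail, upper tail) capped at 1, from
#' either the continuity-corrected normal approximation with
#' tie-corrected variance or exact
#' enumeration of all group-label assignments (feasible for total
#' n <= ~12).
#'
#' @param values named numeric vector (names = sample ids), e.g. a
#'   [module_signature()]
#' @param pheno a [phenotype_table()] with >= 2 ordered groups, all
#'   non-empty
#' @param method `"normal_approx"` (default), `"exact_permutation"`, or
#'   `"auto"` (exact when total n <= 12)
#' @return list of class `trend_test` with `statistic`, `null_mean`,
#'   `null_var` (normal method), `p_two_sided`, `method`
#' @export
jonckheere_terpstra <- function(values, pheno,
                                method = c("normal_approx",
                                           "exact_permutation", "auto")) {
  method <- match.arg(method)
  stopifnot(inherits(pheno, "phenotype_table"))
  v <- if (is.null(names(values))) {
    if (length(values) != nrow(pheno))
      stop("unnamed 'values' must align with the phenotype table")
    values
  } else values[pheno$sample_id]
  if (anyNA(v)) stop("values missing for some samples")
  g <- droplevels(pheno$group)
  n_g <- as.integer(table(g))
  if (length(n_g) < 2L) stop("need at least 2 ordered groups")
  if (any(n_g == 0L)) stop("every group must be non-empty")
  N <- sum(n_g)
  if (method == "auto")
    method <- if (N <= 12L) "exact_permutation" else "normal_approx"
  jt <- .jt_statistic(v, g)
  if (method == "normal_approx") {
    mom <- .jt_moments(n_g, as.numeric(table(v)))
    # 0.5 continuity correction: the statistic lives on a half-integer
    # lattice, and the corrected tails track the exact permutation
    # distribution much more closely at small n
    if (mom$var <= 0) {  # fully tied data carry no trend information
      p <- 1
    } else {
      sdv <- sqrt(mom$var)
      lo <- stats::pnorm((jt + 0.5 - mom$mean) / sdv)
      hi <- stats::pnorm((jt - 0.5 - mom$mean) / sdv, lower.tail = FALSE)
      p <- min(1, 2 * min(lo, hi))
    }
    res <- list(statistic = jt, null_mean = mom$mean, null_var = mom$var,
                p_two_sided = p, method = "normal_approx")
  } else {
    if (N > 14L)
      stop("exact enumeration infeasible for n = ", N, " (> 14)")
    asg <- .group_assignments(n_g)
    # vectorised: JT of an assignment is the sum of the pairwise
    # comparison matrix over all position pairs in increasing group order
    gpos <- rep(seq_along(n_g), n_g)
    pos_pairs <- which(outer(gpos, gpos, "<"), arr.ind = TRUE)
    Cm <- outer(v, v, "<") + 0.5 * outer(v, v, "==")
    stats_null <- numeric(nrow(asg))
    for (k in seq_len(nrow(pos_pairs)))
      stats_null <- stats_null +
        Cm[cbind(asg[, pos_pairs[k, 1L]], asg[, pos_pairs[k, 2L]])]
    lo <- mean(stats_null <= jt)
    hi <- mean(stats_null >= jt)
    res <- list(statistic = jt, null_mean = mean(stats_null),
                null_var = stats::var(stats_null),
                p_two_sided = min(1, 2 * min(lo, hi)),
                method = "exact_permutation")
  }
  class(res) <- "trend_test"
  res
}

#' @export
print.trend_test <- function(x, ...) {
  cat(sprintf("Jonckheere-Terpstra: JT = %g, two-sided p = %.4g (%s)\n",
              x$statistic, x$p_two_sided, x$method))
  invisible(x)
}

#' Read gene sets in GMT format
#'
#' Tab-separated lines: set name, description, then member genes.
#'
#' @param path file path
#' @return named list of character vectors
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t")
  bad <- which(lengths(parts) < 3L)
  if (length(bad))
    stop("malformed GMT line ", bad[1L], ": need name, description, genes")
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- vapply(parts, `[[`, character(1), 1L)
  if (anyDuplicated(names(sets))) stop("duplicate gene-set names")
  sets
}

#' Hypergeometric gene-set enrichment of a module
#'
#' For each annotation set, the raw p-value is the upper-tail
#' hypergeometric probability of drawing at least the observed overlap k
#' when `|module|` genes are sampled from the universe without
#' replacement; q-values are Benjamini-Hochberg adjusted across all sets
#' tested.
#'
#' @param module character vector of genes, a subset of `universe`
#' @param sets named list of gene sets (each intersected with the
#'   universe before testing)
#' @param universe character vector of background genes
#' @return data.frame with columns `set`, `k` (overlap), `K` (set size in
#'   universe), `n` (module size), `N` (universe size), `p`, `q`
#' @export
enrichment <- function(module, sets, universe) {
  universe <- unique(universe)
  if (length(universe) == 0L) stop("empty universe")
  module <- unique(module)
  outside <- setdiff(module, universe)
  if (length(outside))
    stop("module gene(s) outside the universe: ",
         paste(outside, collapse = ", "))
  n <- length(module)
  N <- length(universe)
  rows <- lapply(names(sets), function(nm) {
    s <- intersect(sets[[nm]], universe)
    K <- length(s)
    k <- length(intersect(module, s))
    p <- stats::phyper(k - 1, m = K, n = N - K, k = n, lower.tail = FALSE)
    data.frame(set = nm, k = k, K = K, n = n, N = N, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out[order(out$p), , drop = FALSE]
}
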