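#' B-score significance settings
#'
#' @param runs independent scoring runs averaged into the final B-score
#'   (default 20, the original evaluation protocol)
#' @param cutoff significance threshold on the B-score (default 0.05,
#'   the value at which gene loss stops growing dramatically in the
#'   glioma cohorts)
#' @param null_samples_per_run Monte Carlo draws used to estimate the
#'   null order statistic inside each run (default 1000)
#' @param seed optional integer passed to `set.seed()` before scoring
#' @return a list of class `significance_config`
#' @export
significance_config <- function(runs = 20L, cutoff = 0.05,
                                null_samples_per_run = 1000L,
                                seed = NULL) {
  stopifnot(runs >= 1L, cutoff > 0, cutoff < 1,
            null_samples_per_run >= 1L)
  structure(list(runs = as.integer(runs), cutoff = cutoff,
                 null_samples_per_run = as.integer(null_samples_per_run),
                 seed = seed),
            class = "significance_config")
}

# Per-node upper-tail probability of drawing >= d intra-module partners:
# the node's k stubs sample without replacement from the 2m - k other
# stubs of the network, S of which belong to the other module members.
.node_tail_prob <- function(d, k, S, other) {
  stats::phyper(d - 1, m = S, n = other, k = k, lower.tail = FALSE)
}

#' B-score of a module under a fixed-internal-edge configuration null
#'
#' Scores how often a module at least as tight as the observed one would
#' arise "by chance" in a degree-preserving random rewiring of the
#' network in which the module-internal edges are held fixed and all
#' remaining connections are shuffled. Per run, each module node i with
#' degree k_i and observed intra-module degree d_i gets the cumulative
#' null probability r_i of drawing at least d_i intra-module partners
#' given k_i and the stub budget of the other module members
#' (a hypergeometric upper tail). The run statistic is the worst-node
#' order statistic max_i r_i — every member must beat chance — and its
#' null distribution is estimated by `null_samples_per_run` Monte Carlo
#' draws of the member internal degrees; the run score is the fraction of
#' null draws whose statistic is at most the observed one. The final
#' B-score is the mean over `runs` runs; small values are significant.
#'
#' A degree-0 member has r_i = 1 and therefore can never let a module be
#' significant. Null draws are taken independently per node, ignoring the
#' (weak, for modules much smaller than the network) coupling of internal
#' degrees through the shared edge budget.
#'
#' @param net a [module_network()]
#' @param members character vector of module node labels; must be a
#'   proper non-empty subset of the nodes
#' @param config a [significance_config()]
#' @return list of class `significance_result` with `b_score`,
#'   `per_run_scores`, `significant`, `cutoff`
#' @export
bscore <- function(net, members, config = significance_config()) {
  stopifnot(inherits(net, "module_network"),
            inherits(config, "significance_config"))
  N <- length(net$nodes)
  idx <- match(members, net$nodes)
  if (anyNA(idx)) stop("unknown node label(s): ",
                       paste(members[is.na(idx)], collapse = ", "))
  q <- length(idx)
  if (q == 0L || q == N)
    stop("degenerate module; B-score undefined for the empty or ",
         "whole-network module")
  if (!is.null(config$seed)) set.seed(config$seed)
  deg <- lengths(net$adj)
  two_m <- sum(deg)
  inC <- logical(N); inC[idx] <- TRUE
  d_obs <- vapply(idx, function(v) sum(inC[net$adj[[v]]]), integer(1))
  k <- deg[idx]
  # stub budget of the *other* members, seen from node i
  S <- sum(k) - k
  other <- pmax(two_m - k - S, 0)
  r_obs <- .node_tail_prob(d_obs, k, S, other)
  t_obs <- max(r_obs)
  nS <- config$null_samples_per_run
  per_run <- vapply(seq_len(config$runs), function(run) {
    # null internal degrees, independently per node
    t_null <- rep(-Inf, nS)
    for (i in seq_len(q)) {
      if (k[i] == 0L) {
        t_null <- pmax(t_null, 1)
        next
      }
      d_null <- stats::rhyper(nS, m = S[i], n = other[i], k = k[i])
      t_null <- pmax(t_null, .node_tail_prob(d_null, k[i], S[i], other[i]))
    }
    mean(t_null <= t_obs)
  }, numeric(1))
  b <- mean(per_run)
  structure(list(b_score = b, per_run_scores = per_run,
                 significant = b < config$cutoff, cutoff = config$cutoff,
                 size = q, statistic = t_obs),
            class = "significance_result")
}

#' @export
print.significance_result <- function(x, ...) {
  cat(sprintf("B-score %.4g over %d runs (size %d): %ssignificant at %g\n",
              x$b_score, length(x$per_run_scores), x$size,
              if (x$significant) "" else "not ", x$cutoff))
  invisible(x)
}

#' Score every module of a set
#'
#' @param net a [module_network()]
#' @param ms a [module_set()]
#' @param config a [significance_config()]
#' @return the `module_set` with a `b_score` vector attached
#' @export
bscore_modules <- function(net, ms, config = significance_config()) {
  stopifnot(inherits(ms, "module_set"))
  if (!is.null(config$seed)) set.seed(config$seed)
  cfg <- config; cfg$seed <- NULL
  ms$b_score <- vapply(ms$modules,
                       function(m) bscore(net, m, cfg)$b_score,
                       numeric(1))
  ms
}

#' Filter a module set by B-score
#'
#' Keeps the modules whose B-score is below the cutoff, preserving order,
#' and reports the retained-gene fraction.
#'
#' @param ms a [module_set()]
#' @param b_scores numeric vector of B-scores, one per module; defaults
#'   to the scores stored on `ms`
#' @param cutoff significance threshold (default 0.05)
#' @return the filtered `module_set`, with attribute `retained_fraction`
#'   (retained genes / total genes in the set)
#' @export
filter_significant <- function(ms, b_scores = ms$b_score, cutoff = 0.05) {
  stopifnot(inherits(ms, "module_set"))
  if (is.null(b_scores) || length(b_scores) != length(ms$modules) ||
      anyNA(b_scores))
    stop("need a B-score for every module")
  keep <- b_scores < cutoff
  total <- sum(lengths(ms$modules))
  out <- module_set(ms$modules[keep], W = ms$W[keep],
                    b_score = b_scores[keep],
                    connected = ms$connected[keep],
                    provenance = ms$provenance)
  attr(out, "retained_fraction") <-
    if (total > 0) sum(lengths(ms$modules[keep])) / total else NA_real_
  out
}
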