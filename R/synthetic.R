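#' Planted-module random network
#'
#' Generates a planted-partition graph: node pairs inside the same
#' planted module are connected independently with probability `p_in`,
#' every other pair (background-background, module-background and
#' module-module across different modules) with probability `p_out`.
#' Dense blocks on a sparse background are the ground truth the module
#' extractor is asked to recover.
#'
#' @param n total node count
#' @param module_sizes integer vector of planted module sizes
#'   (sum <= `n`); remaining nodes are background
#' @param p_in within-module edge probability
#' @param p_out background edge probability (normally <= `p_in`; the
#'   inverted case is allowed with a warning)
#' @param seed optional integer for `set.seed()`
#' @return list with `network` (a [module_network()]), `truth` (list of
#'   planted node-label sets) and `params`
#' @export
planted_module_network <- function(n, module_sizes, p_in, p_out,
                                   seed = NULL) {
  stopifnot(n >= 2L, all(module_sizes >= 1L),
            p_in >= 0, p_in <= 1, p_out >= 0, p_out <= 1)
  if (sum(module_sizes) > n)
    stop("planted module sizes exceed the node count")
  if (p_in < p_out)
    warning("p_in < p_out: planted modules are sparser than background")
  if (!is.null(seed)) set.seed(seed)
  nodes <- sprintf("n%03d", seq_len(n))
  block <- rep(0L, n)  # 0 = background
  at <- 1L
  truth <- vector("list", length(module_sizes))
  for (b in seq_along(module_sizes)) {
    idx <- at:(at + module_sizes[b] - 1L)
    block[idx] <- b
    truth[[b]] <- nodes[idx]
    at <- at + module_sizes[b]
  }
  pair <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  same <- block[pair[, 1L]] != 0L & block[pair[, 1L]] == block[pair[, 2L]]
  p <- ifelse(same, p_in, p_out)
  on <- stats::runif(nrow(pair)) < p
  net <- module_network(cbind(nodes[pair[on, 1L]], nodes[pair[on, 2L]]),
                        nodes = nodes)
  list(network = net, truth = truth,
       params = list(n = n, module_sizes = module_sizes, p_in = p_in,
                     p_out = p_out, seed = seed))
}

#' Block-correlated synthetic expression cohort
#'
#' Equal-correlation factor model: gene g of block b has per-sample value
#' `sqrt(rho) * f_b + sqrt(1 - rho) * eps_g` with the block factor `f_b`
#' and the gene noise `eps_g` independent standard normals, so every
#' within-block gene pair has correlation exactly `rho` and cross-block
#' pairs are uncorrelated. Noise genes are pure standard normal. Samples
#' are split evenly (first groups get the remainder) into the ordered
#' groups of `group_levels`, and `group_shifts` adds a per-group constant
#' to designated blocks, planting a monotone expression trend for the
#' trend test to detect.
#'
#' @param n_samples number of samples (>= 4)
#' @param block_sizes integer vector of correlated-block gene counts
#' @param rho within-block correlation, in [0, 1)
#' @param n_noise_genes number of independent background genes
#' @param group_levels ordered group labels (default a single group
#'   "all", i.e. no phenotype structure)
#' @param group_shifts optional list mapping block index -> numeric
#'   vector of per-group additive shifts (length = number of groups)
#' @param seed optional integer for `set.seed()`
#' @return list with `X` (genes x samples matrix), `pheno`
#'   (a [phenotype_table()]), `truth` (list of block gene-label sets) and
#'   `params`
#' @export
correlated_block_expression <- function(n_samples, block_sizes, rho,
                                        n_noise_genes = 0L,
                                        group_levels = "all",
                                        group_shifts = NULL,
                                        seed = NULL) {
  stopifnot(n_samples >= 4L, rho >= 0, rho < 1,
            all(block_sizes >= 1L), n_noise_genes >= 0L)
  if (!is.null(seed)) set.seed(seed)
  n_groups <- length(group_levels)
  base <- n_samples %/% n_groups
  extra <- n_samples %% n_groups
  gsizes <- rep(base, n_groups) + c(rep(1L, extra), rep(0L, n_groups - extra))
  group <- rep(group_levels, gsizes)
  samples <- sprintf("s%03d", seq_len(n_samples))
  pheno <- phenotype_table(samples, group, levels = group_levels)

  G <- sum(block_sizes) + n_noise_genes
  genes <- sprintf("g%04d", seq_len(G))
  X <- matrix(stats::rnorm(G * n_samples), G, n_samples,
              dimnames = list(genes, samples))
  truth <- vector("list", length(block_sizes))
  at <- 1L
  for (b in seq_along(block_sizes)) {
    idx <- at:(at + block_sizes[b] - 1L)
    f_b <- stats::rnorm(n_samples)
    X[idx, ] <- sqrt(rho) * matrix(f_b, length(idx), n_samples,
                                   byrow = TRUE) +
      sqrt(1 - rho) * X[idx, , drop = FALSE]
    if (!is.null(group_shifts) && length(group_shifts) >= b &&
        !is.null(group_shifts[[b]])) {
      sh <- group_shifts[[b]]
      if (length(sh) != n_groups)
        stop("group_shifts[[", b, "]] must have one value per group")
      X[idx, ] <- X[idx, , drop = FALSE] +
        matrix(rep(sh, gsizes), length(idx), n_samples, byrow = TRUE)
    }
    truth[[b]] <- genes[idx]
    at <- at + block_sizes[b]
  }
  list(X = X, pheno = pheno, truth = truth,
       params = list(n_samples = n_samples, block_sizes = block_sizes,
                     rho = rho, n_noise_genes = n_noise_genes,
                     group_levels = group_levels,
                     group_shifts = group_shifts, seed = seed))
}
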