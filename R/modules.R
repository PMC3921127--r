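#' Module set container
#'
#' Holds an ordered collection of pairwise-disjoint node-set modules,
#' optionally annotated with the criterion value at extraction, the
#' extraction order, a connectivity diagnostic and a B-score.
#'
#' @param modules list of character vectors (module member labels)
#' @param W numeric vector of criterion values at extraction (or `NA`)
#' @param b_score numeric vector of B-scores (or `NULL`)
#' @param connected logical vector: was each module connected at
#'   extraction? (`NA` when unknown)
#' @param provenance free-form string identifying the source network and
#'   configuration
#' @return object of class `module_set`
#' @export
module_set <- function(modules, W = rep(NA_real_, length(modules)),
                       b_score = NULL,
                       connected = rep(NA, length(modules)),
                       provenance = "") {
  stopifnot(is.list(modules))
  modules <- lapply(modules, as.character)
  all_nodes <- unlist(modules, use.names = FALSE)
  if (anyDuplicated(all_nodes))
    stop("modules must be pairwise disjoint; node(s) repeated: ",
         paste(unique(all_nodes[duplicated(all_nodes)]), collapse = ", "))
  if (length(modules) &&
      (is.null(names(modules)) || any(!nzchar(names(modules)))))
    names(modules) <- paste0("M", seq_along(modules))
  stopifnot(length(W) == length(modules),
            length(connected) == length(modules))
  if (!is.null(b_score)) stopifnot(length(b_score) == length(modules))
  structure(
    list(modules = modules, W = as.numeric(W), b_score = b_score,
         connected = as.logical(connected), provenance = provenance),
    class = "module_set"
  )
}

#' @export
print.module_set <- function(x, ...) {
  cat("module_set: ", length(x$modules), " module(s), sizes [",
      paste(lengths(x$modules), collapse = ", "), "]\n", sep = "")
  invisible(x)
}

#' @export
length.module_set <- function(x) length(x$modules)

#' Sizes of the modules in a set
#' @param ms a `module_set`
#' @return named integer vector of member counts
#' @export
module_sizes <- function(ms) {
  stopifnot(inherits(ms, "module_set"))
  lengths(ms$modules)
}

#' Read a module-set TSV
#'
#' Expected columns: `module_id`, `node_id`, optionally `W` and
#' `b_score` (constant within a module). Modules keep the order of first
#' appearance of their id. A node assigned to two modules is an error.
#'
#' @param path file path
#' @return a `module_set`
#' @export
read_modules <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (!all(c("module_id", "node_id") %in% colnames(df)))
    stop("module file needs 'module_id' and 'node_id' columns: ", path)
  ids <- unique(df$module_id)
  mods <- lapply(ids, function(id) df$node_id[df$module_id == id])
  names(mods) <- as.character(ids)
  first <- df[!duplicated(df$module_id), , drop = FALSE]
  W <- if ("W" %in% colnames(df)) as.numeric(first$W) else
    rep(NA_real_, length(ids))
  b <- if ("b_score" %in% colnames(df)) as.numeric(first$b_score) else NULL
  module_set(mods, W = W, b_score = b, provenance = path)
}

#' Write a module-set TSV
#' @param ms a `module_set`
#' @param path file path
#' @return `path`, invisibly
#' @export
write_modules <- function(ms, path) {
  stopifnot(inherits(ms, "module_set"))
  sizes <- lengths(ms$modules)
  df <- data.frame(
    module_id = rep(names(ms$modules), sizes),
    node_id = unlist(ms$modules, use.names = FALSE),
    stringsAsFactors = FALSE
  )
  if (!all(is.na(ms$W))) df$W <- rep(ms$W, sizes)
  if (!is.null(ms$b_score)) df$b_score <- rep(ms$b_score, sizes)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
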