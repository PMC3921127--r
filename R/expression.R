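#' Read a gene expression matrix
#'
#' Expects a TSV or CSV file whose first column holds gene identifiers and
#' whose header row holds sample identifiers; the body must be fully
#' numeric (log2-scale intensities). The separator is sniffed from the
#' file extension (".csv" means comma) unless given explicitly.
#'
#' @param path file path
#' @param sep field separator; default sniffed from the extension
#' @return numeric matrix, genes in rows (rownames), samples in columns
#'   (colnames)
#' @export
read_expression_matrix <- function(path, sep = NULL) {
  if (is.null(sep))
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = NA, comment.char = "")
  if (ncol(df) < 2L) stop("expression file needs gene column + samples: ", path)
  genes <- as.character(df[[1L]])
  if (anyDuplicated(genes))
    stop("duplicate gene ID(s): ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "))
  body <- df[, -1L, drop = FALSE]
  for (j in seq_along(body)) {
    col <- body[[j]]
    if (!is.numeric(col)) {
      suppressWarnings(num <- as.numeric(col))
      bad <- which(is.na(num) & !is.na(col))
      if (length(bad))
        stop("non-numeric value at gene '", genes[bad[1L]],
             "', sample '", colnames(body)[j], "'")
      body[[j]] <- num
    }
  }
  X <- as.matrix(body)
  rownames(X) <- genes
  if (anyDuplicated(colnames(X))) stop("duplicate sample ID(s)")
  if (anyNA(X) || any(!is.finite(X)))
    stop("expression matrix contains missing or non-finite values")
  X
}

#' Write a gene expression matrix
#' @param X numeric matrix with gene rownames and sample colnames
#' @param path file path
#' @param sep field separator (default tab)
#' @return `path`, invisibly
#' @export
write_expression_matrix <- function(X, path, sep = "\t") {
  stopifnot(is.matrix(X), !is.null(rownames(X)), !is.null(colnames(X)))
  df <- data.frame(gene_id = rownames(X), X, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}
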