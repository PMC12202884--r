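#' Read a genes x cells expression matrix
#'
#' Two on-disk layouts are supported: a dense tab-separated table (gene rows,
#' first column gene identifiers, header row of cell identifiers) and
#' MatrixMarket coordinate format with one-column `genes.tsv` /
#' `barcodes.tsv` sidecar files. Identifiers are preserved in file order and
#' the matrix is returned dense, genes in rows and cells in columns --- the
#' orientation every function in this package expects.
#'
#' @param path Path to the TSV file or the `.mtx` file.
#' @param format `"tsv"` (dense) or `"mtx"` (MatrixMarket triplet).
#' @param genes_file,cells_file Sidecar paths for `format = "mtx"`; default
#'   `genes.tsv` and `barcodes.tsv` next to the matrix file.
#' @return Numeric matrix with gene rownames and cell colnames.
#' @seealso [write_matrix()]
#' @export
read_expression <- function(path, format = c("tsv", "mtx"),
                            genes_file = NULL, cells_file = NULL) {
  format <- match.arg(format)
  if (format == "tsv") {
    tab <- utils::read.delim(path, check.names = FALSE,
                             stringsAsFactors = FALSE)
    genes <- as.character(tab[[1]])
    m <- as.matrix(tab[, -1, drop = FALSE])
    storage.mode(m) <- "double"
  } else {
    genes_file <- genes_file %||% file.path(dirname(path), "genes.tsv")
    cells_file <- cells_file %||% file.path(dirname(path), "barcodes.tsv")
    m <- as.matrix(Matrix::readMM(path))
    genes <- readLines(genes_file)
    cells <- readLines(cells_file)
    if (nrow(m) != length(genes))
      stop_("matrix has ", nrow(m), " rows but ", length(genes),
            " gene identifiers in ", genes_file)
    if (ncol(m) != length(cells))
      stop_("matrix has ", ncol(m), " columns but ", length(cells),
            " cell identifiers in ", cells_file)
    colnames(m) <- cells
  }
  dup <- genes[duplicated(genes)]
  if (length(dup)) stop_("duplicate gene identifier: ", dup[1])
  rownames(m) <- genes
  if (anyDuplicated(colnames(m)))
    stop_("duplicate cell identifier: ",
          colnames(m)[duplicated(colnames(m))][1])
  if (!all(is.finite(m))) stop_("non-finite expression values in ", path)
  m
}

#' Write a genes x cells matrix (expression or ODM)
#'
#' Inverse of [read_expression()]: dense TSV or MatrixMarket triplet with
#' `genes.tsv` / `barcodes.tsv` sidecars. Values round-trip exactly for
#' integers and to within 1e-9 relative error for reals.
#'
#' @param m Numeric matrix with gene rownames and cell colnames.
#' @param path Output path (the `.mtx` path when `format = "mtx"`).
#' @param format `"tsv"` or `"mtx"`.
#' @export
write_matrix <- function(m, path, format = c("tsv", "mtx")) {
  format <- match.arg(format)
  if (!is.matrix(m) || nrow(m) == 0 || ncol(m) == 0)
    stop_("cannot write an empty matrix")
  if (is.null(rownames(m)) || is.null(colnames(m)))
    stop_("matrix must carry gene rownames and cell colnames")
  if (format == "tsv") {
    tab <- data.frame(gene = rownames(m), m, check.names = FALSE,
                      stringsAsFactors = FALSE)
    utils::write.table(tab, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    Matrix::writeMM(Matrix::Matrix(m, sparse = TRUE), path)
    writeLines(rownames(m), file.path(dirname(path), "genes.tsv"))
    writeLines(colnames(m), file.path(dirname(path), "barcodes.tsv"))
  }
  invisible(path)
}

#' Library-size normalization with optional log transform
#'
#' Scales every cell column to a common total (`scale_factor`), then applies
#' `log(x + 1)` when `log_transform` is `TRUE`. This is the standard
#' variance-stabilizing preprocessing applied identically to the reference
#' and objective datasets before any regression. Cells with zero total are
#' left as all-zero columns with a warning.
#'
#' @param expr Nonnegative genes x cells matrix.
#' @param scale_factor Target column sum; default `1e4`.
#' @param log_transform Apply `log1p` after scaling; default `TRUE`.
#' @return Normalized matrix of the same shape.
#' @export
normalize_expression <- function(expr, scale_factor = 1e4,
                                 log_transform = TRUE) {
  stopifnot(is.matrix(expr), is.numeric(scale_factor), scale_factor > 0)
  if (any(expr < 0)) stop_("negative expression values cannot be normalized")
  tot <- colSums(expr)
  zero <- tot == 0
  if (any(zero)) {
    warning(sum(zero), " cell(s) with zero total left as zeros",
            call. = FALSE)
    tot[zero] <- 1
  }
  out <- sweep(expr, 2, tot / scale_factor, "/")
  if (log_transform) out <- log1p(out)
  out
}

#' Filter genes by detection and variance
#'
#' Keeps genes expressed (value > 0) in at least `min_cells_expressed` cells
#' and with across-cell variance at least `min_variance`. Removing invariant
#' genes up front prevents degenerate regressions downstream. Gene order is
#' preserved.
#'
#' @param expr Genes x cells matrix.
#' @param min_cells_expressed Minimum number of cells with nonzero value.
#' @param min_variance Minimum variance across cells.
#' @return The row-filtered matrix.
#' @export
filter_genes <- function(expr, min_cells_expressed = 0, min_variance = 0) {
  stopifnot(is.matrix(expr))
  n_expr <- rowSums(expr > 0)
  v <- apply(expr, 1, stats::var)
  keep <- n_expr >= min_cells_expressed & v >= min_variance
  if (!any(keep)) stop_("no genes pass the filter")
  expr[keep, , drop = FALSE]
}
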