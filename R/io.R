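#' @title Expression-matrix input, output and normalization
#' @name io
#' @description Readers/writers for sparse Matrix-Market (10x-style
#'   directories) and dense delimited expression matrices, library-size
#'   log-normalization, and the expressed-gene filter required before ICP.
#'   Matrices are held cells-as-rows throughout the package; 10x-style files
#'   store genes as rows and are transposed on read.
NULL

# Validate an expression matrix: finite, non-negative, unique ids.
# Returns the matrix as dgCMatrix with dimnames guaranteed.
.validate_expression <- function(X, what = "expression matrix") {
  if (!methods::is(X, "sparseMatrix") && !is.matrix(X))
    stop(what, " must be a matrix or sparseMatrix")
  X <- methods::as(Matrix::Matrix(X, sparse = TRUE), "generalMatrix")
  if (!methods::is(X, "CsparseMatrix"))
    X <- methods::as(X, "CsparseMatrix")
  if (nrow(X) < 2L) stop(what, " must have at least 2 cells (rows)")
  if (ncol(X) < 1L) stop(what, " must have at least 1 gene (column)")
  v <- X@x
  if (length(v) && (any(!is.finite(v)) || any(v < 0)))
    stop(what, " contains negative or non-finite entries")
  if (is.null(rownames(X)))
    rownames(X) <- sprintf("cell_%d", seq_len(nrow(X)))
  if (is.null(colnames(X)))
    colnames(X) <- sprintf("gene_%d", seq_len(ncol(X)))
  if (anyDuplicated(rownames(X))) stop("duplicate cell ids")
  if (anyDuplicated(colnames(X))) stop("duplicate gene ids")
  X
}

.detect_delim <- function(path) {
  first <- readLines(path, n = 1L)
  if (lengths(regmatches(first, gregexpr("\t", first))) > 0) "\t" else ","
}

#' Read an expression matrix
#'
#' Reads either a 10x-style Matrix-Market directory (`matrix.mtx` plus
#' `features.tsv`/`genes.tsv` and `barcodes.tsv`; 2- or 3-column feature
#' files are accepted, the first column is used as gene id) or a dense
#' delimited text file with a header row and ids in the first column.  The
#' delimiter of dense files is auto-detected (tab or comma).
#'
#' @param path directory (for `format = "mtx_dir"`) or file path.
#' @param format `"mtx_dir"` or `"dense_delim"`.
#' @param orientation for dense files: are genes or cells the rows of the
#'   file?  10x convention (`"genes_as_rows"`, the default) is transposed on
#'   read so that the returned matrix is always cells x genes.
#' @return a `dgCMatrix` with cells as rows, genes as columns.
#' @export
read_matrix <- function(path,
                        format = c("mtx_dir", "dense_delim"),
                        orientation = c("genes_as_rows", "cells_as_rows")) {
  format <- match.arg(format)
  orientation <- match.arg(orientation)
  if (format == "mtx_dir") {
    if (!dir.exists(path)) stop("not a directory: ", path)
    mtx <- file.path(path, "matrix.mtx")
    if (!file.exists(mtx)) stop("missing companion file: ", mtx)
    feat <- file.path(path, "features.tsv")
    if (!file.exists(feat)) feat <- file.path(path, "genes.tsv")
    bc <- file.path(path, "barcodes.tsv")
    if (!file.exists(feat))
      stop("missing companion file: features.tsv / genes.tsv in ", path)
    if (!file.exists(bc))
      stop("missing companion file: barcodes.tsv in ", path)
    M <- Matrix::readMM(mtx)  # genes x cells, 1-based triplets
    genes <- read.delim(feat, header = FALSE, stringsAsFactors = FALSE)[[1L]]
    cells <- read.delim(bc, header = FALSE, stringsAsFactors = FALSE)[[1L]]
    if (nrow(M) != length(genes))
      stop("dimension mismatch: matrix has ", nrow(M), " genes but ",
           length(genes), " feature ids")
    if (ncol(M) != length(cells))
      stop("dimension mismatch: matrix has ", ncol(M), " cells but ",
           length(cells), " barcodes")
    dimnames(M) <- list(genes, cells)
    X <- Matrix::t(M)
  } else {
    if (!file.exists(path)) stop("missing input file: ", path)
    sep <- .detect_delim(path)
    df <- read.delim(path, sep = sep, header = TRUE, row.names = 1L,
                     check.names = FALSE, stringsAsFactors = FALSE)
    X <- as.matrix(df)
    if (!is.numeric(X)) stop("non-numeric entries in ", path)
    if (orientation == "genes_as_rows") X <- t(X)
  }
  .validate_expression(X)
}

#' Write an expression matrix
#'
#' Inverse of [read_matrix()]: `"mtx_dir"` writes `matrix.mtx` (genes as
#' rows, 10x convention), `features.tsv` and `barcodes.tsv` into `path`;
#' `"dense_delim"` writes a tab-delimited file with genes as rows.
#'
#' @param X cells x genes matrix.
#' @param path output directory (mtx) or file path (dense).
#' @inheritParams read_matrix
#' @return `path`, invisibly.
#' @export
write_matrix <- function(X, path, format = c("mtx_dir", "dense_delim")) {
  format <- match.arg(format)
  X <- .validate_expression(X)
  if (format == "mtx_dir") {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    Matrix::writeMM(Matrix::t(X), file.path(path, "matrix.mtx"))
    write.table(data.frame(colnames(X), colnames(X)),
                file.path(path, "features.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
    writeLines(rownames(X), file.path(path, "barcodes.tsv"))
  } else {
    D <- t(as.matrix(X))  # genes as rows
    df <- data.frame(gene_id = rownames(D), format(D, digits = 17,
                                                   scientific = FALSE,
                                                   trim = TRUE),
                     check.names = FALSE)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Library-size log-normalization of UMI counts
#'
#' Entry (i, j) of the result is `log(1 + scale_factor * count_ij / total_i)`
#' where `total_i` is the summed counts of cell i.  Zero entries stay zero,
#' so the sparsity pattern is preserved, and scaling all counts of a cell by
#' a constant leaves its normalized profile unchanged.
#'
#' @param counts cells x genes matrix of non-negative integer UMI counts.
#' @param scale_factor positive scale applied after library-size division
#'   (default 10000).
#' @return normalized matrix of the same shape and sparsity pattern.
#' @export
log_normalize <- function(counts, scale_factor = 1e4) {
  stopifnot(is.numeric(scale_factor), length(scale_factor) == 1L,
            scale_factor > 0)
  X <- .validate_expression(counts, "count matrix")
  if (length(X@x) && any(abs(X@x - round(X@x)) > 1e-8))
    stop("count matrix must contain non-negative integers; ",
         "pass already-normalized data through unchanged instead")
  totals <- Matrix::rowSums(X)
  if (any(totals == 0))
    stop("cell(s) with zero total count: ",
         paste(utils::head(rownames(X)[totals == 0], 5L), collapse = ", "))
  Y <- Matrix::Diagonal(x = scale_factor / totals) %*% X
  Y <- methods::as(methods::as(Y, "CsparseMatrix"), "generalMatrix")
  Y@x <- log1p(Y@x)
  dimnames(Y) <- dimnames(X)
  Y
}

#' Remove genes expressed in no cell
#'
#' ICP requires every gene column to be expressed in at least one cell.
#' This drops all-zero gene columns and reports their ids; it is idempotent.
#'
#' @param X cells x genes matrix.
#' @return list with elements `matrix` (filtered) and `removed`
#'   (character vector of dropped gene ids).
#' @export
apply_gene_filter <- function(X) {
  X <- .validate_expression(X)
  expressed <- Matrix::colSums(X > 0) > 0
  if (!any(expressed)) stop("no expressed genes remain after filtering")
  list(matrix = X[, expressed, drop = FALSE],
       removed = colnames(X)[!expressed])
}
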