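# Gene-expression matrix I/O: MatrixMarket trio (matrix.mtx, barcodes.tsv,
# features.tsv) as written by cellranger, held as a sparse cells x genes
# Matrix::dgCMatrix with barcode/gene dimnames.

#' Read a cellranger-style MTX trio
#'
#' The MatrixMarket file stores genes x cells (cellranger convention); the
#' returned matrix is transposed to cells x genes. Features files may carry
#' one column (symbol) or the 10x three columns (id, symbol, type); the
#' symbol column is used as the gene axis.
#'
#' @param matrix_path MatrixMarket coordinate file.
#' @param barcodes_path one barcode per line.
#' @param features_path one feature per line (1 or 3 tab-separated columns).
#' @return sparse `dgCMatrix`, cells in rows, genes in columns.
#' @export
read_counts <- function(matrix_path, barcodes_path, features_path) {
  m <- Matrix::readMM(matrix_path)
  barcodes <- readLines(barcodes_path)
  feat <- utils::read.delim(features_path, header = FALSE,
                            stringsAsFactors = FALSE)
  genes <- if (ncol(feat) >= 2) feat[[2]] else feat[[1]]
  if (ncol(m) != length(barcodes)) {
    abort_cs(sprintf(
      "barcode count mismatch: matrix declares %d cells, barcodes file has %d",
      ncol(m), length(barcodes)), "cs_validation_error")
  }
  if (nrow(m) != length(genes)) {
    abort_cs(sprintf(
      "feature count mismatch: matrix declares %d genes, features file has %d",
      nrow(m), length(genes)), "cs_validation_error")
  }
  m <- methods::as(Matrix::t(m), "CsparseMatrix")
  dimnames(m) <- list(barcodes, genes)
  m
}

#' Write a cells x genes sparse matrix as an MTX trio
#'
#' @param m sparse matrix, cells in rows, genes in columns, with dimnames.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_counts <- function(m, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(Matrix::t(m), file.path(dir, "matrix.mtx"))
  writeLines(rownames(m), file.path(dir, "barcodes.tsv"))
  writeLines(colnames(m), file.path(dir, "features.tsv"))
  invisible(dir)
}
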