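#' Read a Matrix Market gene x cell triplet
#'
#' Reads a 10x-style trio of files: a Matrix Market coordinate file
#' (1-based indices, genes as rows, cells as columns) plus one-ID-per-line
#' gene and barcode files. If an ID file is tab-delimited, the first column
#' is used. Entries absent from the triplet are zeros.
#'
#' @param matrix_path path to the `.mtx` coordinate file.
#' @param genes_path path to the gene ID file (one gene per line).
#' @param barcodes_path path to the cell barcode file (one cell per line).
#' @return an [expression_matrix()] with `scale = "raw"`.
#' @export
read_mtx_triplet <- function(matrix_path, genes_path, barcodes_path) {
  mm <- Matrix::readMM(matrix_path)
  genes <- read_id_file(genes_path)
  cells <- read_id_file(barcodes_path)
  if (nrow(mm) != length(genes)) {
    stop(sprintf("matrix header declares %d genes but '%s' lists %d",
                 nrow(mm), genes_path, length(genes)))
  }
  if (ncol(mm) != length(cells)) {
    stop(sprintf("matrix header declares %d cells but '%s' lists %d",
                 ncol(mm), barcodes_path, length(cells)))
  }
  values <- as.matrix(mm)
  if (any(values < 0)) {
    stop("matrix file contains negative entries; counts must be non-negative")
  }
  expression_matrix(values, gene_ids = genes, cell_ids = cells, scale = "raw")
}

read_id_file <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  vapply(strsplit(lines, "\t", fixed = TRUE), `[[`, character(1), 1L)
}

#' Read a dense delimited expression matrix
#'
#' Expects a header row of cell IDs (first field is the gene-ID column name),
#' a first column of gene IDs, and a numeric body.
#'
#' @param path path to the delimited text file.
#' @param delimiter field delimiter, default tab.
#' @return an [expression_matrix()] with `scale = "raw"`.
#' @export
read_dense <- function(path, delimiter = "\t") {
  tab <- utils::read.table(path, sep = delimiter, header = TRUE,
                           row.names = NULL, check.names = FALSE,
                           colClasses = "character", comment.char = "",
                           quote = "\"", stringsAsFactors = FALSE)
  if (ncol(tab) < 2) stop("dense matrix file needs a gene-ID column and at least one cell column")
  gene_ids <- tab[[1]]
  cell_ids <- colnames(tab)[-1]
  body <- as.matrix(tab[, -1, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(body), dim = dim(body)))
  bad <- which(is.na(num) & !(body %in% c("NA", "NaN")))
  if (length(bad)) {
    ij <- arrayInd(bad[1], dim(body))
    stop(sprintf("non-numeric value '%s' at gene row %d (%s), cell column %d (%s)",
                 body[bad[1]], ij[1], gene_ids[ij[1]], ij[2], cell_ids[ij[2]]))
  }
  expression_matrix(num, gene_ids = gene_ids, cell_ids = cell_ids, scale = "raw")
}

#' Write a dense delimited expression matrix
#'
#' @param m an [expression_matrix()].
#' @param path output file path.
#' @param delimiter field delimiter, default tab.
#' @param digits significant digits kept in the output (imputed values are
#'   floats; full precision bloats files). Use `digits = NA` for full
#'   precision.
#' @return `path`, invisibly.
#' @export
write_dense <- function(m, path, delimiter = "\t", digits = 6) {
  stopifnot_em(m)
  v <- m$values
  if (!is.na(digits)) v <- signif(v, digits)
  out <- cbind(gene_id = m$gene_ids, as.data.frame(v, check.names = FALSE))
  colnames(out) <- c("gene_id", m$cell_ids)
  utils::write.table(out, path, sep = delimiter, quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Write a Matrix Market gene x cell triplet
#'
#' Explicit zeros are dropped (sparse coordinate convention); the
#' corresponding reader restores them as 0.
#'
#' @param m an [expression_matrix()].
#' @param matrix_path,genes_path,barcodes_path output paths.
#' @return `matrix_path`, invisibly.
#' @export
write_mtx_triplet <- function(m, matrix_path, genes_path, barcodes_path) {
  stopifnot_em(m)
  sp <- methods::as(Matrix::Matrix(m$values, sparse = TRUE), "generalMatrix")
  Matrix::writeMM(sp, matrix_path)
  writeLines(m$gene_ids, genes_path)
  writeLines(m$cell_ids, barcodes_path)
  invisible(matrix_path)
}

#' Write an imputed expression matrix
#'
#' Refuses matrices with non-finite entries, reporting their count and the
#' first offending position. `format = "dense"` writes a single delimited
#' file preserving all (non-sparse) imputed values; `format = "mtx"` writes
#' a `matrix.mtx`/`genes.tsv`/`barcodes.tsv` triplet into the directory
#' `path` (created if needed).
#'
#' @param m an [expression_matrix()].
#' @param path output file (dense) or directory (mtx).
#' @param format `"dense"` or `"mtx"`.
#' @param digits significant digits for dense output (see [write_dense()]).
#' @param delimiter delimiter for dense output.
#' @return the path written, invisibly.
#' @export
write_imputed <- function(m, path, format = c("dense", "mtx"),
                          digits = 6, delimiter = "\t") {
  format <- match.arg(format)
  stopifnot_em(m)
  nf <- which(!is.finite(m$values))
  if (length(nf)) {
    ij <- arrayInd(nf[1], dim(m$values))
    stop(sprintf("refusing to write %d non-finite values; first at gene %s, cell %s",
                 length(nf), m$gene_ids[ij[1]], m$cell_ids[ij[2]]))
  }
  if (format == "dense") {
    write_dense(m, path, delimiter = delimiter, digits = digits)
  } else {
    if (!dir.exists(path)) dir.create(path, recursive = TRUE)
    write_mtx_triplet(m,
                      file.path(path, "matrix.mtx"),
                      file.path(path, "genes.tsv"),
                      file.path(path, "barcodes.tsv"))
  }
  invisible(path)
}

#' Read / write per-cell label files
#'
#' One label per line, aligned to the barcodes file of the same dataset.
#'
#' @param path label file path.
#' @return character vector of labels.
#' @export
read_labels <- function(path) {
  lines <- readLines(path)
  lines[nzchar(lines)]
}

#' @rdname read_labels
#' @param labels character vector to write.
#' @export
write_labels <- function(labels, path) {
  writeLines(as.character(labels), path)
  invisible(path)
}

#' Read / write a per-gene bulk median expression vector
#'
#' Two-column delimited text: gene ID and median bulk expression. Used by
#' the true-zero analysis ([zero_fraction_by_bulk_bin()]).
#'
#' @param path file path.
#' @return named numeric vector.
#' @export
read_bulk_median <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           check.names = FALSE, stringsAsFactors = FALSE)
  stats::setNames(as.numeric(tab[[2]]), as.character(tab[[1]]))
}

#' @rdname read_bulk_median
#' @param bulk_median named numeric vector of per-gene bulk medians.
#' @export
write_bulk_median <- function(bulk_median, path) {
  utils::write.table(
    data.frame(gene_id = names(bulk_median), bulk_median = as.numeric(bulk_median)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
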