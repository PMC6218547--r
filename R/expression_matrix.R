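#' Construct an expression matrix
#'
#' The central container of the package: a dense genes x cells matrix of
#' non-negative expression values together with gene and cell identifiers,
#' optional per-cell type labels, and a `scale` tag recording where the matrix
#' sits in the preprocessing pipeline (`"raw"` counts, library-size
#' `"normalized"`, or `"log"`-transformed).
#'
#' Genes are always rows and cells are always columns, matching the 10x
#' Matrix Market convention. The `scale` tag is advanced only by the
#' preprocessing operations ([median_normalize()], [log_transform()]).
#'
#' @param values numeric matrix, genes x cells.
#' @param gene_ids character vector of unique gene identifiers, one per row.
#'   Defaults to `rownames(values)`.
#' @param cell_ids character vector of unique cell identifiers, one per
#'   column. Defaults to `colnames(values)`.
#' @param cell_labels optional character vector of per-cell type annotations,
#'   one per column.
#' @param scale one of `"raw"`, `"normalized"`, `"log"`.
#' @return an object of class `expression_matrix`: a list with elements
#'   `values`, `gene_ids`, `cell_ids`, `cell_labels`, `scale`.
#' @export
expression_matrix <- function(values, gene_ids = rownames(values),
                              cell_ids = colnames(values),
                              cell_labels = NULL,
                              scale = c("raw", "normalized", "log")) {
  scale <- match.arg(scale)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(gene_ids) || is.null(cell_ids)) {
    stop("gene_ids and cell_ids are required (or set dimnames on `values`)")
  }
  gene_ids <- as.character(gene_ids)
  cell_ids <- as.character(cell_ids)
  if (length(gene_ids) != nrow(values)) {
    stop(sprintf("matrix has %d rows but %d gene IDs were given",
                 nrow(values), length(gene_ids)))
  }
  if (length(cell_ids) != ncol(values)) {
    stop(sprintf("matrix has %d columns but %d cell IDs were given",
                 ncol(values), length(cell_ids)))
  }
  if (anyDuplicated(gene_ids)) {
    stop("duplicate gene IDs: ",
         paste(unique(gene_ids[duplicated(gene_ids)])[1:min(3, sum(duplicated(gene_ids)))],
               collapse = ", "))
  }
  if (anyDuplicated(cell_ids)) {
    stop("duplicate cell IDs: ",
         paste(unique(cell_ids[duplicated(cell_ids)])[1], collapse = ", "))
  }
  if (!is.null(cell_labels)) {
    cell_labels <- as.character(cell_labels)
    if (length(cell_labels) != ncol(values)) {
      stop(sprintf("%d cell labels for %d cells", length(cell_labels), ncol(values)))
    }
  }
  if (scale %in% c("raw", "normalized")) {
    if (any(values < 0, na.rm = TRUE)) {
      stop(sprintf("%s-scale expression values must be non-negative", scale))
    }
  }
  dimnames(values) <- list(gene_ids, cell_ids)
  structure(
    list(values = values, gene_ids = gene_ids, cell_ids = cell_ids,
         cell_labels = cell_labels, scale = scale),
    class = "expression_matrix"
  )
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d genes x %d cells [%s scale]%s\n",
              nrow(x$values), ncol(x$values), x$scale,
              if (is.null(x$cell_labels)) "" else
                sprintf(", %d label groups", length(unique(x$cell_labels)))))
  invisible(x)
}

#' Number of genes / cells in an expression matrix
#' @param m an `expression_matrix`.
#' @return integer count.
#' @export
n_genes <- function(m) nrow(m$values)

#' @rdname n_genes
#' @export
n_cells <- function(m) ncol(m$values)

# internal: replace values and/or scale, keeping ids and labels
em_replace <- function(m, values = m$values, scale = m$scale,
                       gene_ids = NULL) {
  if (is.null(gene_ids)) gene_ids <- m$gene_ids
  expression_matrix(values, gene_ids = gene_ids, cell_ids = m$cell_ids,
                    cell_labels = m$cell_labels, scale = scale)
}

stopifnot_em <- function(m, scale = NULL, arg = "m") {
  if (!inherits(m, "expression_matrix")) {
    stop(sprintf("`%s` must be an expression_matrix", arg))
  }
  if (!is.null(scale) && !(m$scale %in% scale)) {
    stop(sprintf("`%s` must be on the %s scale, got '%s'",
                 arg, paste(scale, collapse = "/"), m$scale))
  }
  invisible(TRUE)
}
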