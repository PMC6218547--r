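#' Preprocessing configuration
#'
#' Defaults follow the standard scRNA-seq pipeline: drop genes not detected
#' with at least `min_reads` reads in at least `min_cells` cells, rescale
#' every cell to the median library size, keep the `n_top_genes` genes with
#' the highest coefficient of variation, then log-transform with a pseudo
#' count.
#'
#' @param min_reads minimum read count for a gene to count as detected in a
#'   cell (default 3).
#' @param min_cells minimum number of detecting cells for a gene to be kept
#'   (default 3).
#' @param n_top_genes number of high-dispersion genes retained (default 1000).
#' @param pseudo_count pseudo count added before the log (default 1).
#' @param log_base base of the log transform (default 2).
#' @return a `preprocess_config` list.
#' @export
preprocess_config <- function(min_reads = 3, min_cells = 3, n_top_genes = 1000,
                              pseudo_count = 1, log_base = 2) {
  stopifnot(min_reads >= 1, min_cells >= 1, n_top_genes >= 1,
            pseudo_count > 0, log_base > 1)
  structure(list(min_reads = min_reads, min_cells = min_cells,
                 n_top_genes = n_top_genes, pseudo_count = pseudo_count,
                 log_base = log_base),
            class = "preprocess_config")
}

#' Filter undetected genes
#'
#' A gene is considered expressed if it is detected with at least `min_reads`
#' reads in at least `min_cells` cells; all other genes are removed. Gene
#' order and the cell axis are untouched.
#'
#' @param m a raw-scale [expression_matrix()].
#' @param min_reads,min_cells detection thresholds (see [preprocess_config()]).
#' @return the filtered `expression_matrix`.
#' @export
filter_genes <- function(m, min_reads = 3, min_cells = 3) {
  stopifnot_em(m, scale = "raw")
  keep <- rowSums(m$values >= min_reads) >= min_cells
  if (!any(keep)) {
    stop(sprintf(paste0("no gene is detected with >= %d reads in >= %d cells; ",
                        "relax min_reads/min_cells"), min_reads, min_cells))
  }
  em_replace(m, values = m$values[keep, , drop = FALSE],
             gene_ids = m$gene_ids[keep])
}

#' Median library-size normalization
#'
#' Divides each cell's counts by that cell's total and multiplies by the
#' median of the totals across cells, so every column sums to the median
#' library size.
#'
#' @param m a raw-scale [expression_matrix()].
#' @return an `expression_matrix` with `scale = "normalized"`.
#' @export
median_normalize <- function(m) {
  stopifnot_em(m, scale = "raw")
  totals <- colSums(m$values)
  zero <- totals == 0
  if (any(zero)) {
    stop("cells with zero total counts cannot be normalized: ",
         paste(m$cell_ids[zero][seq_len(min(5, sum(zero)))], collapse = ", "))
  }
  med <- stats::median(totals)
  v <- sweep(m$values, 2, med / totals, `*`)
  em_replace(m, values = v, scale = "normalized")
}

# population standard deviation (divide by n)
pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

# per-gene coefficient of variation; genes with mean 0 get CV 0
gene_cv <- function(values) {
  mu <- rowMeans(values)
  sdv <- sqrt(rowMeans(values^2) - mu^2)
  sdv[sdv < 0 | is.na(sdv)] <- 0
  ifelse(mu > 0, sdv / mu, 0)
}

#' Select high-dispersion genes
#'
#' Keeps the `k` genes with the highest coefficient of variation (population
#' standard deviation divided by mean, across cells) on the normalized
#' matrix. Ties are broken in favour of the earlier gene; selected genes
#' keep their original order. If fewer than `k` genes exist, all are kept.
#'
#' @param m a normalized-scale [expression_matrix()].
#' @param k number of genes to keep.
#' @return the pruned `expression_matrix`.
#' @export
select_top_dispersion_genes <- function(m, k = 1000) {
  stopifnot_em(m, scale = "normalized")
  if (k < 1) stop("k must be >= 1")
  ng <- n_genes(m)
  if (ng <= k) return(m)
  cv <- gene_cv(m$values)
  # order() is stable: equal CVs fall back to original gene order
  idx <- sort(order(-cv)[seq_len(k)])
  em_replace(m, values = m$values[idx, , drop = FALSE],
             gene_ids = m$gene_ids[idx])
}

#' Log-transform an expression matrix
#'
#' Each entry becomes `log(x + pseudo_count)` in the given base; with the
#' default pseudo count of 1 zeros map to 0.
#'
#' @param m a normalized-scale [expression_matrix()].
#' @param pseudo_count pseudo count (default 1).
#' @param base log base (default 2).
#' @return an `expression_matrix` with `scale = "log"`.
#' @export
log_transform <- function(m, pseudo_count = 1, base = 2) {
  stopifnot_em(m, scale = "normalized")
  if (any(m$values < 0)) stop("log_transform requires non-negative values")
  em_replace(m, values = log(m$values + pseudo_count) / log(base),
             scale = "log")
}

#' Run the full preprocessing pipeline
#'
#' Applies, in order: gene filtering, median library-size normalization,
#' high-dispersion gene selection, log transformation. The accompanying
#' report records the gene count after each step, the median library size,
#' and the selected gene IDs.
#'
#' @param m a raw-scale [expression_matrix()].
#' @param cfg a [preprocess_config()].
#' @return a list with elements `matrix` (log-scale `expression_matrix`) and
#'   `report`.
#' @export
preprocess_pipeline <- function(m, cfg = preprocess_config()) {
  stopifnot_em(m, scale = "raw")
  n_in <- n_genes(m)
  filtered <- filter_genes(m, cfg$min_reads, cfg$min_cells)
  normalized <- median_normalize(filtered)
  selected <- select_top_dispersion_genes(normalized, cfg$n_top_genes)
  logged <- log_transform(selected, cfg$pseudo_count, cfg$log_base)
  report <- list(
    n_genes_in = n_in,
    n_genes_after_filter = n_genes(filtered),
    n_genes_after_select = n_genes(selected),
    n_cells = n_cells(m),
    median_total = stats::median(colSums(filtered$values)),
    selected_gene_ids = selected$gene_ids
  )
  list(matrix = logged, report = report)
}
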