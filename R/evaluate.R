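#' Mask a fraction of the non-zero entries
#'
#' Chooses `round(fraction * nnz)` distinct non-zero positions uniformly at
#' random (without replacement) and sets them to zero, emulating additional
#' dropout. Deterministic per seed.
#'
#' @param m an [expression_matrix()] with at least one non-zero entry.
#' @param fraction fraction of non-zero entries to mask, in (0,1).
#' @param seed RNG seed.
#' @return list with `masked` (the masked `expression_matrix`) and
#'   `positions` (data frame with `gene_index`, `cell_index`, `gene_id`,
#'   `cell_id`, and the linear `index`).
#' @export
mask_nonzero_entries <- function(m, fraction, seed = 1) {
  stopifnot_em(m)
  stopifnot(fraction > 0, fraction < 1)
  nz <- which(m$values != 0)
  if (length(nz) == 0) stop("matrix has no non-zero entries")
  k <- round(fraction * length(nz))
  if (k == 0) stop("round(fraction * nnz) is 0: nothing to mask")
  set.seed(seed)
  picked <- sort(sample(nz, k))
  v <- m$values
  v[picked] <- 0
  ij <- arrayInd(picked, dim(v))
  positions <- data.frame(
    gene_index = ij[, 1], cell_index = ij[, 2],
    gene_id = m$gene_ids[ij[, 1]], cell_id = m$cell_ids[ij[, 2]],
    index = picked, stringsAsFactors = FALSE)
  list(masked = em_replace(m, values = v), positions = positions)
}

#' Expression-recovery error metrics
#'
#' Computed over the masked positions only: normalized mean squared error
#' `NMSE = sum((t - r)^2) / sum(t^2)`, root mean squared error and mean
#' absolute error between truth `t` and recovered `r`.
#'
#' @param truth the full (unmasked) [expression_matrix()].
#' @param recovered the imputed `expression_matrix`, same shape.
#' @param positions positions data frame (or vector of linear indices) from
#'   [mask_nonzero_entries()].
#' @return named numeric vector `c(nmse, rmse, mae)`.
#' @export
recovery_metrics <- function(truth, recovered, positions) {
  stopifnot_em(truth, arg = "truth")
  stopifnot_em(recovered, arg = "recovered")
  if (!identical(dim(truth$values), dim(recovered$values))) {
    stop("truth and recovered matrices have different shapes")
  }
  idx <- if (is.data.frame(positions)) positions$index else as.integer(positions)
  if (length(idx) == 0) stop("no positions to evaluate")
  t <- truth$values[idx]
  r <- recovered$values[idx]
  ss_t <- sum(t^2)
  if (ss_t == 0) stop("truth is zero at every masked position: NMSE undefined")
  d <- t - r
  c(nmse = sum(d^2) / ss_t, rmse = sqrt(mean(d^2)), mae = mean(abs(d)))
}

#' Per-gene-mean baseline imputation
#'
#' Fills every zero entry of a gene with the mean of that gene's non-zero
#' entries (0 if the gene has none). A naive reference point for the
#' masking experiment.
#'
#' @param m an [expression_matrix()].
#' @return the imputed `expression_matrix`.
#' @export
impute_gene_mean <- function(m) {
  stopifnot_em(m)
  v <- m$values
  nnz <- rowSums(v != 0)
  gm <- ifelse(nnz > 0, rowSums(v) / nnz, 0)
  zero <- which(v == 0)
  v[zero] <- gm[((zero - 1) %% nrow(v)) + 1]
  em_replace(m, values = v)
}

#' Masking-based expression-recovery experiment
#'
#' For each masking fraction and run: mask that fraction of the non-zero
#' entries of the processed matrix, train the autoencoder on the masked
#' matrix, impute, and compute NMSE/RMSE/MAE at the masked positions against
#' the unmasked matrix. The per-gene-mean baseline is evaluated on the
#' identical masks. Defaults mirror the standard protocol: fractions 10-50%
#' and 10 runs per fraction.
#'
#' @param processed log-scale [expression_matrix()] (preprocess raw input
#'   first; the masked and truth matrices must share one gene set).
#' @param fractions masking fractions in (0,1).
#' @param n_runs runs per fraction (fresh mask and weight init each run).
#' @param hidden_size,lambda_reg model hyperparameters.
#' @param cfg a [train_config()]; its seed is re-derived per run.
#' @param seed base seed from which per-run mask/init seeds are derived.
#' @param baseline also evaluate the per-gene-mean baseline?
#' @return data frame with one row per fraction x run: `fraction`, `run`,
#'   `seed`, `nmse`, `rmse`, `mae`, and (if `baseline`) `nmse_base`,
#'   `rmse_base`, `mae_base`.
#' @export
masking_experiment <- function(processed,
                               fractions = c(0.1, 0.2, 0.3, 0.4, 0.5),
                               n_runs = 10, hidden_size = 2000,
                               lambda_reg = 1, cfg = train_config(),
                               seed = 1, baseline = TRUE) {
  stopifnot_em(processed, scale = "log")
  stopifnot(all(fractions > 0), all(fractions < 1), n_runs >= 1)
  rows <- list()
  for (fi in seq_along(fractions)) {
    f <- fractions[fi]
    for (run in seq_len(n_runs)) {
      run_seed <- (seed * 1009L + fi * 131L + run) %% 2147483647L
      msk <- mask_nonzero_entries(processed, f, seed = run_seed)
      run_cfg <- cfg
      run_cfg$seed <- (run_seed + 7L) %% 2147483647L
      fit <- fit_autoencoder(msk$masked, hidden_size = hidden_size,
                             lambda_reg = lambda_reg, cfg = run_cfg)
      imp <- impute_matrix(msk$masked, fit$params, keep_observed = FALSE)
      met <- recovery_metrics(processed, imp, msk$positions)
      row <- data.frame(fraction = f, run = run, seed = run_seed,
                        nmse = met[["nmse"]], rmse = met[["rmse"]],
                        mae = met[["mae"]])
      if (baseline) {
        base <- impute_gene_mean(msk$masked)
        bmet <- recovery_metrics(processed, base, msk$positions)
        row$nmse_base <- bmet[["nmse"]]
        row$rmse_base <- bmet[["rmse"]]
        row$mae_base <- bmet[["mae"]]
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  do.call(rbind, rows)
}

#' Aggregate a masking experiment
#'
#' @param results data frame from [masking_experiment()].
#' @return data frame with per-fraction mean and variance of each metric.
#' @export
summarize_masking <- function(results) {
  metrics <- setdiff(colnames(results), c("fraction", "run", "seed"))
  out <- lapply(split(results, results$fraction), function(d) {
    row <- data.frame(fraction = d$fraction[1], n_runs = nrow(d))
    for (mname in metrics) {
      row[[paste0(mname, "_mean")]] <- mean(d[[mname]])
      row[[paste0(mname, "_var")]] <- stats::var(d[[mname]])
      if (nrow(d) == 1) row[[paste0(mname, "_var")]] <- 0
    }
    row
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Hubert-Arabie adjusted Rand index
#'
#' Chance-corrected agreement between two partitions of the same items;
#' 1 for identical partitions, about 0 for random agreement.
#'
#' @param a,b label vectors of equal length.
#' @return the ARI, in \[-1, 1\].
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stop("label vectors differ in length")
  tab <- table(a, b)
  n <- length(a)
  choose2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(choose2(tab))
  sum_a <- sum(choose2(rowSums(tab)))
  sum_b <- sum(choose2(colSums(tab)))
  total <- choose2(n)
  expected <- sum_a * sum_b / total
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(0)
  (sum_ij - expected) / (max_index - expected)
}

#' k-means clustering accuracy against known labels
#'
#' Clusters cells (features = genes, typically on the log scale) with
#' k-means, `K` set to the number of unique labels, keeping the best of
#' `n_restarts` seeded restarts by total within-cluster sum of squares, and
#' returns the adjusted Rand index between the k-means assignment and the
#' labels.
#'
#' @param m an [expression_matrix()].
#' @param labels per-cell labels (length `n_cells`, at least 2 unique).
#' @param n_restarts number of k-means restarts (default 10).
#' @param seed RNG seed for the restarts.
#' @return the ARI, in \[-1, 1\].
#' @export
kmeans_ari <- function(m, labels, n_restarts = 10, seed = 1) {
  stopifnot_em(m)
  if (length(labels) != n_cells(m)) {
    stop(sprintf("%d labels for %d cells", length(labels), n_cells(m)))
  }
  K <- length(unique(labels))
  if (K < 2) stop("need at least 2 unique labels")
  if (n_cells(m) < K) stop("fewer cells than clusters")
  set.seed(seed)
  km <- stats::kmeans(t(m$values), centers = K, nstart = n_restarts,
                      iter.max = 100)
  adjusted_rand_index(km$cluster, labels)
}

#' Per-gene coefficient of variation within a cell subset
#'
#' Ratio of the population standard deviation to the mean of each gene
#' across the given cells; genes with mean 0 report CV 0. With
#' `antilog = TRUE` (for log-scale input) entries are first mapped back to
#' the normalized scale via `base^x - pseudo_count`.
#'
#' @param m an [expression_matrix()].
#' @param cell_subset cell IDs or column indices (default: all cells).
#' @param antilog undo the log transform first? Requires `scale == "log"`.
#' @param base,pseudo_count parameters of the log transform being undone.
#' @return named numeric vector of per-gene CVs.
#' @export
cv_per_gene <- function(m, cell_subset = NULL, antilog = FALSE,
                        base = 2, pseudo_count = 1) {
  stopifnot_em(m)
  if (is.null(cell_subset)) cell_subset <- seq_len(n_cells(m))
  if (is.character(cell_subset)) {
    cell_subset <- match(cell_subset, m$cell_ids)
    if (anyNA(cell_subset)) stop("unknown cell IDs in cell_subset")
  }
  if (length(cell_subset) == 0) stop("cell_subset is empty")
  v <- m$values[, cell_subset, drop = FALSE]
  if (antilog) {
    stopifnot_em(m, scale = "log")
    v <- base^v - pseudo_count
    v[v < 0] <- 0
  }
  stats::setNames(gene_cv(v), m$gene_ids)
}

#' Cell-type separability: 2D PCA + mean silhouette
#'
#' Centers genes, projects cells onto the top two principal components
#' (each component's largest-magnitude loading is made positive for
#' reproducible coordinates), and returns the mean silhouette coefficient
#' of the cells under Euclidean distance in that 2D space. Cells in
#' singleton label groups contribute silhouette 0.
#'
#' @param m an [expression_matrix()] with at least 3 cells.
#' @param labels per-cell labels with at least 2 unique values.
#' @return list with `coords` (cells x 2 matrix) and `mean_silhouette`.
#' @export
separability_silhouette <- function(m, labels) {
  stopifnot_em(m)
  if (length(labels) != n_cells(m)) stop("label / cell count mismatch")
  if (length(unique(labels)) < 2) stop("need at least 2 unique labels")
  if (n_cells(m) < 3) stop("need at least 3 cells")
  pc <- stats::prcomp(t(m$values), rank. = 2, center = TRUE, scale. = FALSE)
  rot <- pc$rotation
  coords <- pc$x[, 1:2, drop = FALSE]
  for (j in 1:2) {
    if (rot[which.max(abs(rot[, j])), j] < 0) coords[, j] <- -coords[, j]
  }
  sil <- cluster::silhouette(as.integer(factor(labels)),
                             dist = stats::dist(coords))
  list(coords = coords, mean_silhouette = mean(sil[, "sil_width"]))
}

#' Zero fractions by bulk-expression bin
#'
#' Separates true zeros from candidate dropouts using a matched bulk
#' reference: genes with zero bulk median form a dedicated "silent" bin;
#' the remaining genes are partitioned into `n_bins` equal-width bins over
#' their bulk median expression. For each bin the fraction of (near-)zero
#' entries in the single-cell matrix is reported, along with its natural
#' log (`NA` and flagged when the fraction is 0). An entry counts as zero
#' when it is `<= zero_threshold`, so reconstructions can be assessed with
#' a small positive threshold.
#'
#' @param sc an [expression_matrix()].
#' @param bulk_median per-gene bulk median expression, aligned to
#'   `sc$gene_ids` (matched by name when named).
#' @param n_bins number of equal-width expression bins (default 10).
#' @param zero_threshold entries at or below this value count as zero.
#' @return data frame with one row per bin: `bin`, `bulk_min`, `bulk_max`,
#'   `n_genes`, `n_entries`, `zero_fraction`, `log_zero_fraction`,
#'   `zero_fraction_is_zero`.
#' @export
zero_fraction_by_bulk_bin <- function(sc, bulk_median, n_bins = 10,
                                      zero_threshold = 0) {
  stopifnot_em(sc, arg = "sc")
  if (!is.null(names(bulk_median))) {
    if (!all(sc$gene_ids %in% names(bulk_median))) {
      stop("bulk_median is missing some of the single-cell gene IDs")
    }
    bulk_median <- bulk_median[sc$gene_ids]
  } else if (length(bulk_median) != n_genes(sc)) {
    stop("bulk_median length does not match the number of genes")
  }
  silent <- bulk_median == 0
  expressed <- which(!silent)
  if (length(expressed) == 0) stop("no genes are expressed in the bulk reference")
  bulk_expr <- bulk_median[expressed]
  breaks <- seq(min(bulk_expr), max(bulk_expr), length.out = n_bins + 1)
  if (breaks[1] == breaks[n_bins + 1]) breaks <- c(breaks[1], breaks[1] + 1)
  bin_of <- findInterval(bulk_expr, breaks, rightmost.closed = TRUE,
                         all.inside = TRUE)
  bin_row <- function(name, genes, lo, hi) {
    entries <- sc$values[genes, , drop = FALSE]
    zf <- if (length(entries)) mean(entries <= zero_threshold) else NA_real_
    data.frame(bin = name, bulk_min = lo, bulk_max = hi,
               n_genes = length(genes), n_entries = length(entries),
               zero_fraction = zf,
               log_zero_fraction = if (!is.na(zf) && zf > 0) log(zf) else NA_real_,
               zero_fraction_is_zero = !is.na(zf) && zf == 0,
               stringsAsFactors = FALSE)
  }
  rows <- list(bin_row("silent", which(silent), 0, 0))
  for (b in seq_len(length(breaks) - 1)) {
    rows[[b + 1]] <- bin_row(sprintf("bin%02d", b),
                             expressed[bin_of == b],
                             breaks[b], breaks[b + 1])
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
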