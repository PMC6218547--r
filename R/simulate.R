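#' Synthetic clustered scRNA-seq configuration
#'
#' Parameters of the count simulator used throughout testing and
#' benchmarking. Defaults describe a modest clustered dataset: 200 genes,
#' 300 cells in 3 equal clusters, low-rank log-mean structure,
#' negative-binomial counts, and 40% expression-dependent dropout.
#'
#' @param n_genes,n_cells matrix dimensions.
#' @param n_clusters number of cell clusters.
#' @param latent_rank rank of the Gaussian factor model behind the
#'   per-cluster gene log-means.
#' @param cluster_proportions cluster membership proportions (sum to 1).
#' @param mean_expression_scale multiplicative scale of the expression
#'   means (counts).
#' @param noise_dispersion negative-binomial size parameter; larger is
#'   closer to Poisson.
#' @param dropout_rate baseline probability that a non-zero entry is zeroed
#'   by dropout, in \[0, 1).
#' @param dropout_shape decay of the dropout probability with the true
#'   count: `P(drop) = dropout_rate * exp(-dropout_shape * value)`.
#' @param n_silent_genes number of genes forced to all-zero (biologically
#'   silent).
#' @param seed RNG seed.
#' @return a `synthetic_config` list.
#' @export
synthetic_config <- function(n_genes = 200, n_cells = 300, n_clusters = 3,
                             latent_rank = 3,
                             cluster_proportions = rep(1 / n_clusters, n_clusters),
                             mean_expression_scale = 5,
                             noise_dispersion = 2,
                             dropout_rate = 0.4, dropout_shape = 0.05,
                             n_silent_genes = round(0.05 * n_genes),
                             seed = 1) {
  stopifnot(n_genes >= 2, n_cells >= 2, n_clusters >= 1,
            latent_rank >= 1, latent_rank <= min(n_genes, n_cells),
            length(cluster_proportions) == n_clusters,
            all(cluster_proportions > 0),
            abs(sum(cluster_proportions) - 1) < 1e-8,
            mean_expression_scale > 0, noise_dispersion > 0,
            dropout_rate >= 0, dropout_rate < 1, dropout_shape >= 0,
            n_silent_genes >= 0, n_silent_genes < n_genes)
  structure(list(n_genes = n_genes, n_cells = n_cells,
                 n_clusters = n_clusters, latent_rank = latent_rank,
                 cluster_proportions = cluster_proportions,
                 mean_expression_scale = mean_expression_scale,
                 noise_dispersion = noise_dispersion,
                 dropout_rate = dropout_rate, dropout_shape = dropout_shape,
                 n_silent_genes = n_silent_genes, seed = seed),
            class = "synthetic_config")
}

# amplitude of the low-rank cluster deviations on the log-mean scale; 0.3
# keeps clusters subtle enough that dropout visibly corrupts k-means, the
# regime dropout imputation is meant for
CLUSTER_SEPARATION <- 0.3

# largest-remainder apportionment: exact cluster sizes for any proportions
apportion <- function(n, proportions) {
  raw <- n * proportions
  counts <- floor(raw)
  short <- n - sum(counts)
  if (short > 0) {
    extra <- order(-(raw - counts))[seq_len(short)]
    counts[extra] <- counts[extra] + 1
  }
  as.integer(counts)
}

#' Generate a clustered single-cell count dataset with dropout
#'
#' The generative model: (1) per-cluster gene means are
#' `mean_expression_scale * exp(b + s L F / sqrt(r))` with a shared
#' standard-Gaussian gene baseline `b` (log-normal spread of expression
#' levels across genes), standard-Gaussian loadings `L` (genes x r) and
#' factors `F` (r x clusters), and a fixed separation amplitude `s = 0.3`
#' keeping the cluster differences subtle; (2) cells are
#' assigned to clusters by largest-remainder rounding of the proportions,
#' so label counts are exact; (3) counts are drawn per entry from a
#' negative binomial with the cell's cluster mean and `noise_dispersion`;
#' (4) `n_silent_genes` rows (the last ones) are forced to all-zero;
#' (5) each non-zero entry is independently zeroed with probability
#' `dropout_rate * exp(-dropout_shape * value)`, so lowly expressed genes
#' drop out more. The bulk reference emulates a dropout-free bulk profile:
#' the per-gene median across cells of the expected (noise-free) expression,
#' which is positive for every expressed gene and 0 exactly on the silent
#' ones.
#'
#' @param cfg a [synthetic_config()].
#' @return a `synthetic_dataset` list: `true` and `observed` raw-scale
#'   [expression_matrix()] objects (the observed one carries the cell
#'   labels), `cell_labels`, `dropout_positions` (data frame with linear
#'   `index` plus gene/cell coordinates), `silent_gene_ids`, and
#'   `bulk_median` (named vector).
#' @export
generate_synthetic <- function(cfg = synthetic_config()) {
  stopifnot(inherits(cfg, "synthetic_config"))
  set.seed(cfg$seed)
  g <- cfg$n_genes; n <- cfg$n_cells; K <- cfg$n_clusters; r <- cfg$latent_rank
  base <- stats::rnorm(g)
  L <- matrix(stats::rnorm(g * r), g, r)
  Fc <- matrix(stats::rnorm(r * K), r, K)
  mu <- cfg$mean_expression_scale *
    exp(base + CLUSTER_SEPARATION * L %*% Fc / sqrt(r))
  sizes <- apportion(n, cfg$cluster_proportions)
  cluster <- rep(seq_len(K), sizes)
  labels <- sprintf("cluster%d", cluster)
  true <- matrix(0, g, n)
  for (j in seq_len(n)) {
    true[, j] <- stats::rnbinom(g, size = cfg$noise_dispersion,
                                mu = mu[, cluster[j]])
  }
  gene_ids <- sprintf("gene%04d", seq_len(g))
  cell_ids <- sprintf("cell%04d", seq_len(n))
  silent_ids <- character(0)
  if (cfg$n_silent_genes > 0) {
    silent_idx <- (g - cfg$n_silent_genes + 1):g
    true[silent_idx, ] <- 0
    silent_ids <- gene_ids[silent_idx]
  }
  observed <- true
  nz <- which(true > 0)
  dropped <- integer(0)
  if (cfg$dropout_rate > 0 && length(nz) > 0) {
    p <- cfg$dropout_rate * exp(-cfg$dropout_shape * true[nz])
    hit <- stats::runif(length(nz)) < p
    dropped <- nz[hit]
    observed[dropped] <- 0
  }
  if (all(observed == 0)) {
    stop("generated observed matrix is all zero; lower dropout_rate or raise mean_expression_scale")
  }
  ij <- arrayInd(dropped, dim(true))
  dropout_positions <- data.frame(
    gene_index = ij[, 1], cell_index = ij[, 2],
    gene_id = gene_ids[ij[, 1]], cell_id = cell_ids[ij[, 2]],
    index = dropped, stringsAsFactors = FALSE)
  # bulk profile: median over cells of each gene's expected expression
  # (bulk has no dropout/count noise, so use the noise-free means)
  bulk_median <- apply(mu[, cluster, drop = FALSE], 1, stats::median)
  if (cfg$n_silent_genes > 0) bulk_median[silent_idx] <- 0
  bulk_median <- stats::setNames(bulk_median, gene_ids)
  structure(list(
    true = expression_matrix(true, gene_ids, cell_ids,
                             cell_labels = labels, scale = "raw"),
    observed = expression_matrix(observed, gene_ids, cell_ids,
                                 cell_labels = labels, scale = "raw"),
    cell_labels = labels,
    dropout_positions = dropout_positions,
    silent_gene_ids = silent_ids,
    bulk_median = bulk_median,
    config = cfg
  ), class = "synthetic_dataset")
}

#' Small pinned synthetic fixture
#'
#' A fixed tiny dataset (50 genes x 60 cells, 3 equal clusters, pinned
#' seed) used across the test suite; stable across releases.
#'
#' @return a `synthetic_dataset` (see [generate_synthetic()]).
#' @export
fixture_small <- function() {
  generate_synthetic(synthetic_config(
    n_genes = 50, n_cells = 60, n_clusters = 3, latent_rank = 2,
    mean_expression_scale = 5, noise_dispersion = 2,
    dropout_rate = 0.3, dropout_shape = 0.05, n_silent_genes = 3,
    seed = 42))
}
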