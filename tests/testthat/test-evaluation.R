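test_that("masking removes the requested number of non-zero entries", {
  v <- rbind(c(1, 0, 2), c(0, 3, 4))  # 4 non-zeros
  m <- tiny_em(v, scale = "log")
  res <- mask_nonzero_entries(m, 0.5, seed = 3)
  expect_identical(nrow(res$positions), 2L)
  expect_true(all(res$masked$values[res$positions$index] == 0))
  expect_identical(sum(res$masked$values != 0), 2L)

  # deterministic per seed
  res2 <- mask_nonzero_entries(m, 0.5, seed = 3)
  expect_identical(res$positions, res2$positions)

  # restoring the masked values reproduces the original exactly
  v2 <- res$masked$values
  v2[res$positions$index] <- m$values[res$positions$index]
  expect_identical(v2, m$values)

  # nnz bookkeeping on a larger random fixture
  set.seed(10)
  big <- tiny_em(matrix(rpois(400, 1), 20, 20), scale = "raw")
  nnz <- sum(big$values != 0)
  r <- mask_nonzero_entries(big, 0.25, seed = 1)
  expect_identical(sum(r$masked$values != 0),
                   as.integer(nnz - round(0.25 * nnz)))

  expect_error(mask_nonzero_entries(m, 0.01, seed = 1), "nothing to mask")
})

test_that("recovery metrics follow the NMSE/RMSE/MAE formulas", {
  t <- tiny_em(rbind(c(2, 4, 6)), scale = "log")
  pos <- 1:3

  expect_equal(unname(recovery_metrics(t, t, pos)), c(0, 0, 0))

  shifted <- t; shifted$values <- t$values + 0.5
  met <- recovery_metrics(t, shifted, pos)
  expect_equal(unname(met[c("rmse", "mae")]), c(0.5, 0.5))

  r <- tiny_em(rbind(c(1, 5, 4)), scale = "log")
  met <- recovery_metrics(t, r, pos)
  expect_equal(met[["nmse"]], (1 + 1 + 4) / (4 + 16 + 36))
  expect_equal(met[["rmse"]], sqrt(mean(c(1, 1, 4))))
  expect_equal(met[["mae"]], mean(c(1, 1, 2)))

  # scaling laws: NMSE invariant, RMSE/MAE linear
  k <- 3.7
  ts <- t; ts$values <- t$values * k
  rs <- r; rs$values <- r$values * k
  ms <- recovery_metrics(ts, rs, pos)
  expect_equal(ms[["nmse"]], met[["nmse"]])
  expect_equal(ms[["rmse"]], k * met[["rmse"]])
  expect_equal(ms[["mae"]], k * met[["mae"]])

  zt <- tiny_em(rbind(c(0, 0, 1)), scale = "log")
  expect_error(recovery_metrics(zt, r, 1:2), "NMSE undefined")
})

test_that("adjusted Rand index matches the contingency formula and mclust", {
  a <- c(1, 1, 1, 2, 2, 3)
  b <- c(2, 2, 3, 3, 1, 1)
  # brute-force Hubert-Arabie evaluation of this 6-item table
  tab <- table(a, b)
  ch2 <- function(x) x * (x - 1) / 2
  sij <- sum(ch2(tab)); sa <- sum(ch2(rowSums(tab))); sb <- sum(ch2(colSums(tab)))
  expected <- sa * sb / ch2(6)
  oracle <- (sij - expected) / ((sa + sb) / 2 - expected)
  expect_equal(adjusted_rand_index(a, b), oracle)
  expect_equal(adjusted_rand_index(a, b), mclust::adjustedRandIndex(a, b))

  # identical partitions up to relabeling
  expect_equal(adjusted_rand_index(a, c("x", "y", "z")[a]), 1)
  # permutation invariance
  expect_equal(adjusted_rand_index(sample(a), rep(1, 6)),
               adjusted_rand_index(a, rep(2, 6)))
})

test_that("kmeans_ari recovers planted clusters and validates inputs", {
  set.seed(21)
  centers <- matrix(c(0, 10, 20), nrow = 5, ncol = 3, byrow = TRUE)
  v <- cbind(centers[, rep(1, 8)], centers[, rep(2, 8)], centers[, rep(3, 8)]) +
    matrix(rnorm(5 * 24, sd = 0.1), 5, 24)
  v <- v - min(v)
  m <- tiny_em(v, scale = "log")
  labels <- rep(c("a", "b", "c"), each = 8)
  expect_equal(kmeans_ari(m, labels, seed = 1), 1)

  expect_error(kmeans_ari(m, labels[1:5]), "24 cells")
  expect_error(kmeans_ari(m, rep("a", 24)), "unique labels")
})

test_that("per-gene CV uses population sd and the anti-log inverts the log", {
  m <- tiny_em(rbind(c(5, 5, 5, 5), c(1, 3, 1, 3)), scale = "log")
  cv <- cv_per_gene(m)
  expect_equal(unname(cv), c(0, 0.5))  # sd(1,3)=1 (population), mean 2

  # anti-log on log2(x+1) data reproduces the CV of the normalized values
  set.seed(4)
  norm <- matrix(runif(40, 0, 20), 8, 5)
  mlog <- tiny_em(log2(norm + 1), scale = "log")
  expect_equal(unname(cv_per_gene(mlog, antilog = TRUE)),
               apply(norm, 1, function(x) sqrt(mean((x - mean(x))^2)) / mean(x)),
               tolerance = 1e-10)

  # zero-mean gene reports 0, subsetting by ID works
  z <- tiny_em(rbind(c(0, 0), c(1, 2)), scale = "log")
  expect_equal(unname(cv_per_gene(z, cell_subset = c("c001", "c002"))[1]), 0)
  expect_error(cv_per_gene(z, cell_subset = "nope"), "unknown cell")
})

test_that("silhouette separability reflects cluster geometry", {
  set.seed(31)
  # two tight, far-separated blobs
  v <- cbind(matrix(rnorm(5 * 10, 0, 0.05), 5),
             matrix(rnorm(5 * 10, 30, 0.05), 5))
  v <- v - min(v)
  m <- tiny_em(v, scale = "log")
  labels <- rep(c("a", "b"), each = 10)
  res <- separability_silhouette(m, labels)
  expect_gt(res$mean_silhouette, 0.9)
  expect_identical(dim(res$coords), c(20L, 2L))

  # random labels on one isotropic blob: near zero
  blob <- tiny_em(matrix(rnorm(5 * 40, 10), 5, 40), scale = "log")
  sils <- vapply(1:5, function(s) {
    set.seed(s)
    separability_silhouette(blob, sample(rep(c("a", "b"), 20)))$mean_silhouette
  }, numeric(1))
  expect_lt(max(abs(sils)), 0.1)

  # duplicating every cell leaves the mean silhouette essentially unchanged
  # (not exactly: each point gains a zero-distance neighbour in its own
  # cluster, perturbing the intra-cluster mean at order 1/n)
  dup <- expression_matrix(cbind(v, v), m$gene_ids,
                           c(m$cell_ids, paste0(m$cell_ids, "_d")),
                           scale = "log")
  expect_equal(separability_silhouette(dup, c(labels, labels))$mean_silhouette,
               res$mean_silhouette, tolerance = 1e-2)

  # singleton label group contributes silhouette 0, not an error
  one <- separability_silhouette(m, c("solo", labels[-1]))
  expect_true(is.finite(one$mean_silhouette))
})

test_that("bulk-binned zero fractions match hand counts", {
  # 6 genes x 4 cells with hand-placed zeros
  v <- rbind(c(0, 0, 0, 0),   # silent in bulk
             c(1, 0, 2, 0),   # low bulk bin: 2/4 zeros
             c(0, 1, 1, 1),   # low bulk bin: 1/4 zeros
             c(5, 6, 7, 8),   # high bulk bin: 0/4
             c(9, 0, 9, 9),   # high bulk bin: 1/4
             c(4, 4, 0, 4))   # low bulk bin: 1/4
  sc <- tiny_em(v, scale = "raw")
  bulk <- c(0, 1, 1.5, 10, 9, 2)
  names(bulk) <- sc$gene_ids
  res <- zero_fraction_by_bulk_bin(sc, bulk, n_bins = 2)
  expect_identical(res$bin, c("silent", "bin01", "bin02"))
  expect_equal(res$n_genes, c(1L, 3L, 2L))
  # silent gene is all-zero: fraction 1, ln = 0
  expect_equal(res$zero_fraction[1], 1)
  expect_equal(res$log_zero_fraction[1], 0)
  # low bin: genes 2,3,6 -> 4 zeros of 12; high bin: genes 4,5 -> 1 of 8
  expect_equal(res$zero_fraction[2], 4 / 12)
  expect_equal(res$zero_fraction[3], 1 / 8)

  # a bin with no zeros is flagged for log reporting
  nz <- tiny_em(rbind(c(1, 2), c(3, 4)), scale = "raw")
  res2 <- zero_fraction_by_bulk_bin(nz, c(g001 = 1, g002 = 5), n_bins = 1)
  expect_equal(res2$zero_fraction[2], 0)
  expect_true(res2$zero_fraction_is_zero[2])
  expect_true(is.na(res2$log_zero_fraction[2]))

  expect_error(zero_fraction_by_bulk_bin(sc, rep(0, 6)), "expressed")
})

test_that("gene-mean baseline fills zeros with the observed gene mean", {
  m <- tiny_em(rbind(c(2, 0, 4), c(0, 0, 0)), scale = "log")
  out <- impute_gene_mean(m)
  expect_equal(unname(out$values), rbind(c(2, 3, 4), c(0, 0, 0)))
})

test_that("masking experiment aggregates per-fraction runs", {
  ds <- fixture_small()
  pre <- preprocess_pipeline(ds$observed, preprocess_config(n_top_genes = 30))$matrix
  res <- masking_experiment(pre, fractions = 0.2, n_runs = 1,
                            hidden_size = 40, lambda_reg = 1,
                            cfg = train_config(learning_rate = 1e-3,
                                               threshold = 1e-3,
                                               max_iters = 40),
                            seed = 2)
  expect_identical(nrow(res), 1L)
  expect_true(all(res[, c("nmse", "rmse", "mae")] >= 0))
  summ <- summarize_masking(res)
  expect_identical(summ$n_runs, 1L)
  expect_equal(summ$nmse_var, 0)
  expect_equal(summ$nmse_mean, res$nmse)
})
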