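# shared fixtures and independent oracles for the suite

# quick expression_matrix with auto-generated ids
tiny_em <- function(values, scale = "raw", labels = NULL) {
  values <- as.matrix(values)
  expression_matrix(values,
                    gene_ids = sprintf("g%03d", seq_len(nrow(values))),
                    cell_ids = sprintf("c%03d", seq_len(ncol(values))),
                    cell_labels = labels, scale = scale)
}

# randomized sparse model instance for loss/gradient checks
rand_instance <- function(seed, g = 6, n = 5, hidden = 4, lambda = 0.5,
                          zero_frac = 0.4, init_std = 0.1) {
  set.seed(seed)
  R <- matrix(runif(g * n, 0.5, 3), g, n)
  R[sample(g * n, round(zero_frac * g * n))] <- 0
  if (all(R == 0)) R[1, 1] <- 1
  M <- (R != 0) * 1
  params <- init_params(g, hidden_size = hidden, lambda_reg = lambda,
                        seed = seed + 1000, init_std = init_std)
  list(R = R, M = M, params = params)
}

# brute-force double-loop evaluation of the masked loss
brute_force_loss <- function(params, R, M) {
  H <- 1 / (1 + exp(-(params$E %*% (R * M))))
  Xhat <- params$D %*% H
  acc <- 0
  for (i in seq_len(nrow(R))) {
    for (j in seq_len(ncol(R))) {
      if (M[i, j] == 1) acc <- acc + (R[i, j] - Xhat[i, j])^2
    }
  }
  acc + params$lambda_reg / 2 * (sum(params$E^2) + sum(params$D^2))
}

# central finite-difference gradients of masked_loss
fd_gradients <- function(params, R, M, h = 1e-5) {
  fd_one <- function(which) {
    W <- params[[which]]
    G <- array(0, dim(W))
    for (k in seq_along(W)) {
      pp <- params; pp[[which]][k] <- W[k] + h
      pm <- params; pm[[which]][k] <- W[k] - h
      G[k] <- (masked_loss(pp, R, M) - masked_loss(pm, R, M)) / (2 * h)
    }
    G
  }
  list(grad_E = fd_one("E"), grad_D = fd_one("D"))
}

rel_err <- function(a, b) {
  sqrt(sum((a - b)^2)) / max(sqrt(sum(b^2)), .Machine$double.eps)
}

# rank-2 fully observed instance used by the training-contract checks
rank2_instance <- function(seed = 99, g = 20, n = 30) {
  set.seed(seed)
  U <- matrix(runif(g * 2, 0.5, 1.5), g, 2)
  V <- matrix(runif(2 * n, 0.5, 1.5), 2, n)
  R <- U %*% V
  list(R = R, M = (R != 0) * 1,
       em = tiny_em(R, scale = "log"))
}

# training configs used for the synthetic-study protocols (see the methods
# vignette): a strongly regularized one for masking recovery and a mild one
# for clustering / variance / zero-retention analyses
recovery_cfg <- function(seed = 1) {
  train_config(learning_rate = 1e-3, threshold = 1e-4, max_iters = 1000,
               seed = seed)
}
recovery_hidden <- 128
recovery_lambda <- 100

cluster_cfg <- function(seed = 1) {
  train_config(learning_rate = 1e-3, threshold = 1e-3, max_iters = 500,
               seed = seed)
}
cluster_hidden <- 300
cluster_lambda <- 1
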