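#' Observed-entry mask
#'
#' Binary indicator matrix with 1 exactly where the processed matrix is
#' non-zero. The reconstruction loss is evaluated only at these observed
#' positions, so the many zeros (candidate dropouts) never penalize the fit.
#'
#' @param processed a log-scale [expression_matrix()].
#' @return a 0/1 numeric matrix with the same shape as `processed$values`.
#' @export
build_observed_mask <- function(processed) {
  stopifnot_em(processed, scale = "log")
  M <- (processed$values != 0) * 1
  if (sum(M) == 0) stop("matrix has no non-zero entries: nothing observed to fit")
  M
}

#' Initialize autoencoder parameters
#'
#' Encoder `E` (hidden x features) and decoder `D` (features x hidden) are
#' drawn i.i.d. from Normal(0, init_std^2), deterministically per seed
#' (`E` is filled first, then `D`). The layer is overcomplete whenever
#' `hidden_size > n_features`. The trainable parameter count is exactly
#' `2 * n_features * hidden_size` (no bias terms).
#'
#' @param n_features number of input/output nodes (genes in the processed
#'   matrix).
#' @param hidden_size width of the hidden layer.
#' @param lambda_reg Tikhonov regularization weight on `E` and `D`.
#' @param seed RNG seed for the initialization.
#' @param init_std standard deviation of the initial weights.
#' @return an `ae_params` list with elements `E`, `D`, `lambda_reg`,
#'   `hidden_size`, `n_features`.
#' @export
init_params <- function(n_features, hidden_size = 2000, lambda_reg = 1,
                        seed = 1, init_std = 0.01) {
  stopifnot(n_features >= 1, hidden_size >= 1, lambda_reg >= 0, init_std > 0)
  set.seed(seed)
  E <- matrix(stats::rnorm(hidden_size * n_features, 0, init_std),
              hidden_size, n_features)
  D <- matrix(stats::rnorm(n_features * hidden_size, 0, init_std),
              n_features, hidden_size)
  structure(list(E = E, D = D, lambda_reg = lambda_reg,
                 hidden_size = hidden_size, n_features = n_features),
            class = "ae_params")
}

#' Training configuration
#'
#' Full-batch gradient descent with RMSProp step scaling; training stops
#' once the change in loss between consecutive iterations drops below
#' `threshold`, with `max_iters` as a safety cap.
#'
#' @param learning_rate RMSProp base learning rate.
#' @param threshold convergence tolerance on the loss change.
#' @param max_iters safety cap on iterations.
#' @param rmsprop_decay accumulator decay rho in (0,1).
#' @param rmsprop_epsilon denominator stabilizer.
#' @param seed seed used by [fit_autoencoder()] for the weight init.
#' @param init_std standard deviation of the weight init.
#' @return a `train_config` list.
#' @export
train_config <- function(learning_rate = 1e-4, threshold = 1e-4,
                         max_iters = 5000, rmsprop_decay = 0.9,
                         rmsprop_epsilon = 1e-8, seed = 1, init_std = 0.01) {
  stopifnot(learning_rate > 0, threshold > 0, max_iters >= 1,
            rmsprop_decay > 0, rmsprop_decay < 1, rmsprop_epsilon > 0,
            init_std > 0)
  structure(list(learning_rate = learning_rate, threshold = threshold,
                 max_iters = max_iters, rmsprop_decay = rmsprop_decay,
                 rmsprop_epsilon = rmsprop_epsilon, seed = seed,
                 init_std = init_std),
            class = "train_config")
}

sigmoid <- function(z) 1 / (1 + exp(-z))

check_model_shapes <- function(params, R, M = NULL) {
  if (!inherits(params, "ae_params")) stop("`params` must come from init_params()")
  if (nrow(R) != params$n_features) {
    stop(sprintf("input has %d features but model expects %d",
                 nrow(R), params$n_features))
  }
  if (!is.null(M) && !identical(dim(M), dim(R))) {
    stop("mask and matrix shapes differ")
  }
  invisible(TRUE)
}

#' Forward pass of the autoencoder
#'
#' Computes the reconstruction `Xhat = D %*% sigmoid(E %*% R)`: a sigmoid
#' encoder followed by a linear decoder. Columns are samples (cells), rows
#' are features (genes).
#'
#' @param params an `ae_params` object.
#' @param R features x samples input matrix.
#' @return the reconstructed matrix, same shape as `R`.
#' @export
forward_pass <- function(params, R) {
  check_model_shapes(params, R)
  params$D %*% sigmoid(params$E %*% R)
}

# shared forward computation for loss and gradients; input is masked once so
# entries at M = 0 can never influence the fit
ae_forward_parts <- function(params, R, M) {
  Rin <- R * M
  H <- sigmoid(params$E %*% Rin)
  Xhat <- params$D %*% H
  Err <- (Xhat - R) * M
  list(Rin = Rin, H = H, Err = Err)
}

ae_loss_from_parts <- function(params, parts) {
  sum(parts$Err^2) +
    params$lambda_reg / 2 * (sum(params$E^2) + sum(params$D^2))
}

#' Masked reconstruction loss
#'
#' Sum of squared reconstruction errors over observed (mask = 1) entries
#' plus the Tikhonov penalty `lambda/2 * (||E||_F^2 + ||D||_F^2)`. Entries
#' at mask-0 positions never contribute: the network input is masked before
#' the forward pass and residuals are masked after it.
#'
#' @param params an `ae_params` object.
#' @param R features x samples matrix.
#' @param M observed mask from [build_observed_mask()].
#' @return a finite scalar loss.
#' @export
masked_loss <- function(params, R, M) {
  check_model_shapes(params, R, M)
  loss <- ae_loss_from_parts(params, ae_forward_parts(params, R, M))
  if (!is.finite(loss)) stop("masked loss is non-finite (overflow)")
  loss
}

#' Analytic gradients of the masked loss
#'
#' Back-propagation through the single hidden layer. With `Z = E Rin`,
#' `H = sigmoid(Z)` and `Err = M * (D H - R)`:
#' `grad_D = 2 Err t(H) + lambda D` and
#' `grad_E = 2 (t(D) Err * H (1 - H)) t(Rin) + lambda E`.
#'
#' @inheritParams masked_loss
#' @return list with elements `grad_E` and `grad_D`.
#' @export
loss_gradients <- function(params, R, M) {
  check_model_shapes(params, R, M)
  parts <- ae_forward_parts(params, R, M)
  grad_D <- 2 * parts$Err %*% t(parts$H) + params$lambda_reg * params$D
  delta <- crossprod(params$D, parts$Err) * parts$H * (1 - parts$H)
  grad_E <- 2 * delta %*% t(parts$Rin) + params$lambda_reg * params$E
  list(grad_E = grad_E, grad_D = grad_D)
}

new_train_state <- function(params) {
  structure(list(iteration = 0L, loss_history = numeric(0),
                 acc_E = array(0, dim(params$E)), acc_D = array(0, dim(params$D)),
                 converged = FALSE),
            class = "ae_train_state")
}

#' One RMSProp update
#'
#' Elementwise: accumulator `a <- rho a + (1 - rho) g^2`, parameter
#' `theta <- theta - lr * g / (sqrt(a) + eps)`, applied to `E` and `D`.
#'
#' @param params an `ae_params` object.
#' @param grads gradient list from [loss_gradients()].
#' @param state an `ae_train_state` holding the accumulators.
#' @param cfg a [train_config()].
#' @return list with updated `params` and `state`.
#' @export
rmsprop_step <- function(params, grads, state, cfg) {
  rho <- cfg$rmsprop_decay
  eps <- cfg$rmsprop_epsilon
  if (!identical(dim(state$acc_E), dim(params$E)) ||
      !identical(dim(state$acc_D), dim(params$D))) {
    stop("accumulator shapes do not match the parameters")
  }
  state$acc_E <- rho * state$acc_E + (1 - rho) * grads$grad_E^2
  state$acc_D <- rho * state$acc_D + (1 - rho) * grads$grad_D^2
  params$E <- params$E - cfg$learning_rate * grads$grad_E / (sqrt(state$acc_E) + eps)
  params$D <- params$D - cfg$learning_rate * grads$grad_D / (sqrt(state$acc_D) + eps)
  list(params = params, state = state)
}

#' Train the autoencoder
#'
#' Full-batch gradient descent with RMSProp. `loss_history[i]` is the loss
#' at the parameters entering iteration `i`; from the second iteration on,
#' training stops (converged) when two consecutive recorded losses differ
#' by less than `cfg$threshold`, otherwise at `cfg$max_iters`. The loss at
#' the final parameters is appended as the last history entry, so
#' `loss_history` always starts at the initial loss and ends at the final
#' one. Deterministic given the initial parameters and config.
#'
#' @param R features x samples matrix (the processed log expression matrix).
#' @param M observed mask from [build_observed_mask()].
#' @param params initial `ae_params` from [init_params()].
#' @param cfg a [train_config()].
#' @param log_every if > 0, emit a progress message every that many
#'   iterations.
#' @return list with trained `params` and the final `state`.
#' @export
train_autoencoder <- function(R, M, params, cfg = train_config(),
                              log_every = 0) {
  check_model_shapes(params, R, M)
  state <- new_train_state(params)
  history <- numeric(cfg$max_iters + 1L)
  n_rec <- 0L
  for (i in seq_len(cfg$max_iters)) {
    parts <- ae_forward_parts(params, R, M)
    loss_i <- ae_loss_from_parts(params, parts)
    if (!is.finite(loss_i)) {
      last <- if (n_rec > 0) history[n_rec] else NA_real_
      stop(sprintf("training diverged at iteration %d (last finite loss %.6g)",
                   i, last))
    }
    n_rec <- n_rec + 1L
    history[n_rec] <- loss_i
    if (log_every > 0 && (i == 1L || i %% log_every == 0L)) {
      dl <- if (n_rec > 1) abs(history[n_rec] - history[n_rec - 1L]) else NA_real_
      message(sprintf("iter %6d  loss %.6g  |dloss| %.3g", i, loss_i, dl))
    }
    if (i >= 2L && abs(history[n_rec] - history[n_rec - 1L]) < cfg$threshold) {
      state$converged <- TRUE
      state$iteration <- i
      break
    }
    grad_D <- 2 * parts$Err %*% t(parts$H) + params$lambda_reg * params$D
    delta <- crossprod(params$D, parts$Err) * parts$H * (1 - parts$H)
    grad_E <- 2 * delta %*% t(parts$Rin) + params$lambda_reg * params$E
    upd <- rmsprop_step(params, list(grad_E = grad_E, grad_D = grad_D),
                        state, cfg)
    params <- upd$params
    state <- upd$state
    state$iteration <- i
  }
  if (!state$converged) {
    # record the loss at the final parameters
    n_rec <- n_rec + 1L
    history[n_rec] <- masked_loss(params, R, M)
  }
  state$loss_history <- history[seq_len(n_rec)]
  list(params = params, state = state)
}

#' Fit the autoencoder to a processed expression matrix
#'
#' Convenience wrapper: builds the observed mask, initializes parameters
#' from `cfg$seed`/`cfg$init_std`, and trains. The processed gene IDs are
#' stored on the returned parameters so that [impute_matrix()] can verify
#' the gene set.
#'
#' @param processed log-scale [expression_matrix()] from
#'   [preprocess_pipeline()].
#' @param hidden_size hidden-layer width (default 2000).
#' @param lambda_reg regularization weight (default 1).
#' @param cfg a [train_config()].
#' @param log_every see [train_autoencoder()].
#' @return list with `params`, `state`, and the `mask`.
#' @export
fit_autoencoder <- function(processed, hidden_size = 2000, lambda_reg = 1,
                            cfg = train_config(), log_every = 0) {
  stopifnot_em(processed, scale = "log")
  M <- build_observed_mask(processed)
  params <- init_params(n_genes(processed), hidden_size = hidden_size,
                        lambda_reg = lambda_reg, seed = cfg$seed,
                        init_std = cfg$init_std)
  params$gene_ids <- processed$gene_ids
  fit <- train_autoencoder(processed$values, M, params, cfg,
                           log_every = log_every)
  fit$mask <- M
  fit
}

#' Impute a processed expression matrix
#'
#' Runs the trained model forward to obtain predicted values at all
#' positions; negative reconstructions are clipped to 0 (log-scale
#' expression is non-negative). With `keep_observed = TRUE` the observed
#' (non-zero) entries are overwritten with their original values, so only
#' zeros receive imputed values.
#'
#' @param processed log-scale [expression_matrix()] the model was trained on
#'   (same gene set and order).
#' @param params trained `ae_params`.
#' @param keep_observed overwrite observed entries with the input values?
#'   Default `FALSE` (the pure reconstruction).
#' @return a log-scale `expression_matrix` of imputed values.
#' @export
impute_matrix <- function(processed, params, keep_observed = FALSE) {
  stopifnot_em(processed, scale = "log")
  if (!is.null(params$gene_ids) &&
      !identical(params$gene_ids, processed$gene_ids)) {
    stop("gene set of `processed` does not match the genes the model was trained on")
  }
  check_model_shapes(params, processed$values)
  X <- forward_pass(params, processed$values)
  X[X < 0] <- 0
  if (keep_observed) {
    obs <- processed$values != 0
    X[obs] <- processed$values[obs]
  }
  em_replace(processed, values = X, scale = "log")
}
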