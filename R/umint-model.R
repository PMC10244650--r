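#' Configuration for the modular integration network
#'
#' Collects the architecture and training hyperparameters. Defaults follow the
#' published protocol: a 64-unit bottleneck, 25 epochs of Adam with batch
#' size 16, L1 activity coefficient `alpha = 1e-4` and L2 weight coefficient
#' `beta = 1e-3`.
#'
#' @param hidden_widths integer vector n_i, the width of each modality's
#'   encoding module; `NULL` defers to `min(128, max(16, ceiling(d_i / 8)))`
#'   once the input dimensions are known.
#' @param bottleneck_width width k of the shared bottleneck (the embedding
#'   dimension).
#' @param lambdas per-modality reconstruction weights; `"auto"` (default) uses
#'   `1 / d_i`, making each term a per-feature mean squared error so that a
#'   20-feature panel is not drowned out by a 2,000-gene modality.
#' @param alpha L1 coefficient on hidden-layer activities.
#' @param beta L2 coefficient on hidden-layer weights.
#' @param epochs training epochs.
#' @param batch_size minibatch size.
#' @param learning_rate Adam step size.
#' @param seed integer seed controlling initialization and shuffling.
#' @param penalize_input_weights also apply the L2 penalty to the input-layer
#'   weights W_1i (excluded by default: the penalty covers the layers from the
#'   encoding modules onward).
#' @return an object of class `umint_config`.
#' @export
umint_config <- function(hidden_widths = NULL, bottleneck_width = 64,
                         lambdas = "auto", alpha = 1e-4, beta = 1e-3,
                         epochs = 25, batch_size = 16, learning_rate = 1e-3,
                         seed = 1, penalize_input_weights = FALSE) {
  stopifnot(bottleneck_width >= 1, epochs >= 1, batch_size >= 1,
            learning_rate > 0)
  if (alpha < 0 || beta < 0) stop("alpha and beta must be non-negative")
  if (!identical(lambdas, "auto") && any(lambdas <= 0))
    stop("lambdas must be positive")
  if (!is.null(hidden_widths) && any(hidden_widths < 1))
    stop("hidden_widths must be positive")
  structure(list(hidden_widths = hidden_widths,
                 bottleneck_width = as.integer(bottleneck_width),
                 lambdas = lambdas, alpha = alpha, beta = beta,
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, seed = as.integer(seed),
                 penalize_input_weights = isTRUE(penalize_input_weights)),
            class = "umint_config")
}

default_hidden_widths <- function(dims) pmin(128L, pmax(16L, as.integer(ceiling(dims / 8))))

resolve_config <- function(dims, config) {
  m <- length(dims)
  if (is.null(config$hidden_widths))
    config$hidden_widths <- default_hidden_widths(dims)
  if (length(config$hidden_widths) != m)
    stop("hidden_widths length must match the number of modalities")
  if (identical(config$lambdas, "auto")) config$lambdas <- 1 / dims
  if (length(config$lambdas) != m)
    stop("lambdas length must match the number of modalities")
  if (config$bottleneck_width >= sum(dims))
    stop("bottleneck_width must be smaller than the total input dimension")
  config
}

glorot <- function(n_in, n_out) {
  lim <- sqrt(6 / (n_in + n_out))
  matrix(stats::runif(n_in * n_out, -lim, lim), n_in, n_out)
}

#' Build an untrained modular integration model
#'
#' Allocates, per modality i: encoder weights `W1` (d_i x n_i) with bias `b1`,
#' fusion weights `W2` (n_i x k), decoder weights `W3` (k x n_i) with bias
#' `b3`, and reconstruction weights `W4` (n_i x d_i) with bias `b4`; plus one
#' shared bottleneck bias `b2` (length k). Weights use a seeded uniform
#' Glorot initialization; biases start at zero. The same seed always yields
#' bitwise-identical parameters.
#'
#' @param dims integer vector of modality input dimensions d_i.
#' @param config an [umint_config()].
#' @return an object of class `umint_model`.
#' @export
build_umint <- function(dims, config = umint_config()) {
  if (any(dims < 1)) stop("dims must all be >= 1")
  config <- resolve_config(dims, config)
  n <- config$hidden_widths
  k <- config$bottleneck_width
  set.seed(config$seed)
  modules <- lapply(seq_along(dims), function(i) {
    list(W1 = glorot(dims[i], n[i]), b1 = numeric(n[i]),
         W2 = glorot(n[i], k),
         W3 = glorot(k, n[i]), b3 = numeric(n[i]),
         W4 = glorot(n[i], dims[i]), b4 = numeric(dims[i]))
  })
  structure(list(modules = modules, b2 = numeric(k), dims = as.integer(dims),
                 config = config),
            class = "umint_model")
}

#' @export
print.umint_model <- function(x, ...) {
  cat(sprintf("umint_model: %d modalities, dims (%s), hidden (%s), bottleneck %d\n",
              length(x$dims), paste(x$dims, collapse = ","),
              paste(x$config$hidden_widths, collapse = ","),
              x$config$bottleneck_width))
  cat(sprintf("first-layer weights: %d (dense equivalent %d)\n",
              count_parameters_umint(x$dims, x$config$hidden_widths),
              count_parameters_dense(x$dims, x$config$hidden_widths)))
  invisible(x)
}

#' Count weight entries of a built model, layer by layer
#'
#' @param model an `umint_model`.
#' @return named integer vector with entries `first` (input -> encoding
#'   modules), `fuse` (encoding -> bottleneck), `defuse` (bottleneck ->
#'   decoding) and `last` (decoding -> reconstruction).
#' @export
model_weight_counts <- function(model) {
  stopifnot(inherits(model, "umint_model"))
  cnt <- function(nm) sum(vapply(model$modules, function(mod) length(mod[[nm]]),
                                 numeric(1)))
  c(first = cnt("W1"), fuse = cnt("W2"), defuse = cnt("W3"), last = cnt("W4"))
}

relu <- function(x) {
  x[x < 0] <- 0
  x
}

as_matrix_list <- function(data, model = NULL) {
  xs <- if (inherits(data, "PairedDataset"))
    lapply(data$modalities, as_dense)
  else if (inherits(data, "OmicsMatrix")) list(as_dense(data))
  else if (is.matrix(data)) list(data)
  else if (is.list(data))
    lapply(data, function(d) if (inherits(d, "OmicsMatrix")) as_dense(d) else as.matrix(d))
  else stop("unsupported data type")
  if (!is.null(model)) {
    if (length(xs) != length(model$dims))
      stop(sprintf("model expects %d modalities, got %d", length(model$dims),
                   length(xs)))
    for (i in seq_along(xs))
      if (ncol(xs[[i]]) != model$dims[i])
        stop(sprintf("modality %d has %d features but model expects %d",
                     i, ncol(xs[[i]]), model$dims[i]))
  }
  xs
}

data_cell_ids <- function(data) {
  if (inherits(data, "PairedDataset")) data$modalities[[1]]$cell_ids
  else if (inherits(data, "OmicsMatrix")) data$cell_ids
  else if (is.matrix(data) && !is.null(rownames(data))) rownames(data)
  else if (is.list(data) && inherits(data[[1]], "OmicsMatrix")) data[[1]]$cell_ids
  else NULL
}

# Full forward pass on a list of dense matrices (rows = cells).
umint_forward <- function(model, xs) {
  mods <- model$modules
  m <- length(mods)
  h2 <- vector("list", m)
  a3 <- NULL
  for (i in seq_len(m)) {
    h2[[i]] <- relu(sweep(xs[[i]] %*% mods[[i]]$W1, 2, mods[[i]]$b1, "+"))
    contrib <- h2[[i]] %*% mods[[i]]$W2
    a3 <- if (is.null(a3)) contrib else a3 + contrib
  }
  h3 <- relu(sweep(a3, 2, model$b2, "+"))
  h4 <- vector("list", m)
  xhat <- vector("list", m)
  for (i in seq_len(m)) {
    h4[[i]] <- relu(sweep(h3 %*% mods[[i]]$W3, 2, mods[[i]]$b3, "+"))
    xhat[[i]] <- sweep(h4[[i]] %*% mods[[i]]$W4, 2, mods[[i]]$b4, "+")
  }
  list(h2 = h2, h3 = h3, h4 = h4, xhat = xhat)
}

new_embedding <- function(values, cell_ids = NULL) {
  if (is.null(cell_ids)) cell_ids <- paste0("cell", seq_len(nrow(values)))
  rownames(values) <- cell_ids
  structure(list(values = values, cell_ids = as.character(cell_ids)),
            class = "Embedding")
}

#' @export
print.Embedding <- function(x, ...) {
  cat(sprintf("Embedding: %d cells x %d dimensions\n", nrow(x$values),
              ncol(x$values)))
  invisible(x)
}

#' Encode a paired dataset into the shared bottleneck embedding
#'
#' Runs the encoder: per-modality ReLU encoding modules followed by the fused
#' ReLU bottleneck. Bottleneck activations are non-negative by construction.
#'
#' @param model a built (usually trained) `umint_model`.
#' @param data a `PairedDataset`, list of `OmicsMatrix`/matrices, or a single
#'   matrix for one-modality models.
#' @param with_activations also return the hidden activations (`h2`, `h3`,
#'   `h4`) and reconstructions of a full forward pass.
#' @return an `Embedding`, or (with `with_activations = TRUE`) a list
#'   `list(embedding, activations = list(h2, h3, h4), reconstructions)`.
#' @export
umint_encode <- function(model, data, with_activations = FALSE) {
  xs <- as_matrix_list(data, model)
  fw <- umint_forward(model, xs)
  emb <- new_embedding(fw$h3, data_cell_ids(data))
  if (!with_activations) return(emb)
  list(embedding = emb,
       activations = list(h2 = fw$h2, h3 = fw$h3, h4 = fw$h4),
       reconstructions = fw$xhat)
}

#' Decode an embedding back to per-modality reconstructions
#'
#' Runs the mirrored decoder: per-modality ReLU decoding modules followed by a
#' linear reconstruction layer (no final nonlinearity, so reconstructions are
#' unbounded).
#'
#' @param model an `umint_model`.
#' @param embedding an `Embedding` or a bare n x k matrix.
#' @return list of n x d_i reconstruction matrices, one per modality.
#' @export
umint_decode <- function(model, embedding) {
  h3 <- if (inherits(embedding, "Embedding")) embedding$values else as.matrix(embedding)
  if (ncol(h3) != model$config$bottleneck_width)
    stop(sprintf("embedding width %d does not match bottleneck width %d",
                 ncol(h3), model$config$bottleneck_width))
  lapply(model$modules, function(mod) {
    h4 <- relu(sweep(h3 %*% mod$W3, 2, mod$b3, "+"))
    sweep(h4 %*% mod$W4, 2, mod$b4, "+")
  })
}

#' Evaluate the training objective on a dataset
#'
#' The objective is the sum of (i) per-modality reconstruction terms
#' `lambda_i / n * ||X_i - Xhat_i||_F^2`, (ii) an L1 activity penalty
#' `alpha * (per-cell mean L1 norm of the hidden activations h2, h3, h4)`, and
#' (iii) an L2 weight penalty `beta * sum ||W||_F^2` over the fusion, decoding
#' and reconstruction weights (input-layer weights are excluded unless
#' `penalize_input_weights` is set in the config). The activity penalty is
#' averaged over cells so its meaning does not depend on batch size.
#'
#' @param model an `umint_model`.
#' @param data dataset accepted by [umint_encode()].
#' @param forward optional precomputed forward pass (internal use).
#' @return a list of class `umint_loss` with `reconstruction_terms` (one per
#'   modality), `activity_penalty`, `weight_penalty` and `total`.
#' @export
umint_loss <- function(model, data, forward = NULL) {
  xs <- as_matrix_list(data, model)
  if (is.null(forward)) forward <- umint_forward(model, xs)
  cfg <- model$config
  n <- nrow(xs[[1]])
  lambdas <- cfg$lambdas
  recon <- vapply(seq_along(xs), function(i)
    lambdas[i] / n * sum((xs[[i]] - forward$xhat[[i]])^2), numeric(1))
  act <- sum(vapply(forward$h2, sum, numeric(1))) + sum(forward$h3) +
    sum(vapply(forward$h4, sum, numeric(1)))
  activity <- cfg$alpha * act / n
  w2 <- sum(vapply(model$modules, function(mod)
    sum(mod$W2^2) + sum(mod$W3^2) + sum(mod$W4^2) +
      if (cfg$penalize_input_weights) sum(mod$W1^2) else 0, numeric(1)))
  weight <- cfg$beta * w2
  structure(list(reconstruction_terms = recon, activity_penalty = activity,
                 weight_penalty = weight,
                 total = sum(recon) + activity + weight),
            class = "umint_loss")
}

#' @export
print.umint_loss <- function(x, ...) {
  cat(sprintf("loss %.6g = recon %.6g + activity %.6g + weights %.6g\n",
              x$total, sum(x$reconstruction_terms), x$activity_penalty,
              x$weight_penalty))
  invisible(x)
}

# Analytic gradients of the objective for one batch. Returns the gradient
# list shaped like the parameter list plus the forward pass. The L1 activity
# term is differentiated through the ReLU mask (subgradient 0 at exactly 0).
# For the denoising objective the forward pass runs on `inputs` while the
# squared error is measured against clean `targets`.
umint_gradients <- function(model, inputs, targets = inputs) {
  cfg <- model$config
  mods <- model$modules
  m <- length(mods)
  n <- nrow(inputs[[1]])
  fw <- umint_forward(model, inputs)
  a_over_n <- cfg$alpha / n
  grads <- vector("list", m)
  d3 <- matrix(0, n, cfg$bottleneck_width)
  for (i in seq_len(m)) {
    d5 <- (2 * cfg$lambdas[i] / n) * (fw$xhat[[i]] - targets[[i]])
    gW4 <- crossprod(fw$h4[[i]], d5) + 2 * cfg$beta * mods[[i]]$W4
    gb4 <- colSums(d5)
    d4 <- (d5 %*% t(mods[[i]]$W4) + a_over_n) * (fw$h4[[i]] > 0)
    gW3 <- crossprod(fw$h3, d4) + 2 * cfg$beta * mods[[i]]$W3
    gb3 <- colSums(d4)
    d3 <- d3 + d4 %*% t(mods[[i]]$W3)
    grads[[i]] <- list(W3 = gW3, b3 = gb3, W4 = gW4, b4 = gb4)
  }
  d3 <- (d3 + a_over_n) * (fw$h3 > 0)
  gb2 <- colSums(d3)
  for (i in seq_len(m)) {
    gW2 <- crossprod(fw$h2[[i]], d3) + 2 * cfg$beta * mods[[i]]$W2
    d2 <- (d3 %*% t(mods[[i]]$W2) + a_over_n) * (fw$h2[[i]] > 0)
    gW1 <- crossprod(inputs[[i]], d2)
    if (cfg$penalize_input_weights) gW1 <- gW1 + 2 * cfg$beta * mods[[i]]$W1
    grads[[i]]$W1 <- gW1
    grads[[i]]$b1 <- colSums(d2)
    grads[[i]]$W2 <- gW2
  }
  list(modules = grads, b2 = gb2, forward = fw)
}
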