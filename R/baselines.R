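#' Stack modalities into one wide matrix
#'
#' Horizontal concatenation of the aligned modalities — the input form used by
#' the dense autoencoder baselines. Feature ids are prefixed with their
#' modality tag (`"RNA:GeneX"`) to stay unique.
#'
#' @param data a `PairedDataset`.
#' @return an `OmicsMatrix` of width `sum(d_i)` tagged `"stacked"`.
#' @export
stack_modalities <- function(data) {
  stopifnot(inherits(data, "PairedDataset"))
  mats <- lapply(data$modalities, as_dense)
  feats <- unlist(lapply(data$modalities, function(m)
    paste(m$modality_tag, m$feature_ids, sep = ":")), use.names = FALSE)
  omics_matrix(do.call(cbind, mats), cell_ids = data$modalities[[1]]$cell_ids,
               feature_ids = feats, modality_tag = "stacked",
               is_count = all(vapply(data$modalities, `[[`, logical(1), "is_count")))
}

#' Configuration for the dense autoencoder baselines
#'
#' The baselines share the bottleneck width and training knobs with the
#' modular network so comparisons hold every hyperparameter fixed; only the
#' first layer differs (dense over the stacked input instead of one module per
#' modality).
#'
#' @param variant `"AE"` (plain), `"DAE"` (denoising) or `"SAE"` (sparse).
#' @param hidden_width total first-hidden-layer width; pin this to the sum of
#'   the matched modular network's module widths for exact parameter-count
#'   comparisons.
#' @param bottleneck_width embedding dimension k.
#' @param noise_level DAE only: Gaussian corruption scale, in units of each
#'   feature's standard deviation.
#' @param sparsity_alpha SAE only: L1 coefficient on hidden activations.
#' @param noise_type DAE corruption model: `"gaussian"` (additive, scaled by
#'   per-feature sd) or `"mask"` (random zeroing with probability
#'   `noise_level`).
#' @param beta,epochs,batch_size,learning_rate,seed shared training knobs, as
#'   in [umint_config()].
#' @return an object of class `baseline_config`.
#' @export
baseline_config <- function(variant = c("AE", "DAE", "SAE"), hidden_width,
                            bottleneck_width = 64, noise_level = 0.1,
                            sparsity_alpha = 1e-4,
                            noise_type = c("gaussian", "mask"), beta = 1e-3,
                            epochs = 25, batch_size = 16, learning_rate = 1e-3,
                            seed = 1) {
  variant <- match.arg(variant)
  noise_type <- match.arg(noise_type)
  stopifnot(hidden_width >= 1, noise_level >= 0, sparsity_alpha >= 0)
  structure(list(variant = variant, hidden_width = as.integer(hidden_width),
                 bottleneck_width = as.integer(bottleneck_width),
                 noise_level = noise_level, sparsity_alpha = sparsity_alpha,
                 noise_type = noise_type, beta = beta,
                 epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, seed = as.integer(seed)),
            class = "baseline_config")
}

baseline_umint_config <- function(config) {
  umint_config(hidden_widths = config$hidden_width,
               bottleneck_width = config$bottleneck_width, lambdas = 1,
               alpha = if (config$variant == "SAE") config$sparsity_alpha else 0,
               beta = config$beta, epochs = config$epochs,
               batch_size = config$batch_size,
               learning_rate = config$learning_rate, seed = config$seed)
}

#' Build an untrained dense autoencoder baseline
#'
#' A dense encoder `d_total -> hidden_width -> k` with mirrored decoder —
#' structurally the one-modality special case of the modular network, which is
#' exactly how it is built here (so the training loop, initialization and
#' regularization are identical by construction).
#'
#' @param d_total stacked input width.
#' @param config a [baseline_config()].
#' @return an `umint_model` with a single dense module; the baseline variant
#'   is recorded in the `"variant"` attribute.
#' @export
build_baseline <- function(d_total, config) {
  stopifnot(inherits(config, "baseline_config"))
  if (config$bottleneck_width >= d_total)
    stop("bottleneck_width must be smaller than the input width")
  model <- build_umint(d_total, baseline_umint_config(config))
  attr(model, "variant") <- config$variant
  model
}

#' Train a dense autoencoder baseline
#'
#' AE: plain mean squared reconstruction error plus the shared L2 weight
#' penalty. DAE: inputs corrupted during training only (additive Gaussian
#' noise scaled by each feature's standard deviation, or random masking), loss
#' measured against the clean targets. SAE: adds an L1 penalty on hidden
#' activations. All variants use the same optimizer, epochs and batch size as
#' the matched modular network.
#'
#' @param x stacked input: an `OmicsMatrix` (see [stack_modalities()]) or a
#'   plain matrix.
#' @param config a [baseline_config()].
#' @param verbose print per-epoch loss.
#' @return an `umint_fit` whose model has one dense module; the variant is
#'   recorded in the `"variant"` attribute of the fit.
#' @export
train_baseline <- function(x, config, verbose = FALSE) {
  stopifnot(inherits(config, "baseline_config"))
  xm <- if (inherits(x, "OmicsMatrix")) as_dense(x) else as.matrix(x)
  corrupt <- NULL
  if (config$variant == "DAE" && config$noise_level > 0) {
    if (config$noise_type == "gaussian") {
      feature_sd <- apply(xm, 2, stats::sd)
      corrupt <- function(batch) {
        b <- batch[[1]]
        noise <- matrix(stats::rnorm(length(b)), nrow(b)) *
          rep(config$noise_level * feature_sd, each = nrow(b))
        list(b + noise)
      }
    } else {
      corrupt <- function(batch) {
        b <- batch[[1]]
        mask <- matrix(stats::runif(length(b)) >= config$noise_level, nrow(b))
        list(b * mask)
      }
    }
  }
  fit <- train_umint(list(xm), baseline_umint_config(config),
                     corrupt = corrupt, verbose = verbose)
  if (inherits(x, "OmicsMatrix")) fit$cell_ids <- x$cell_ids
  attr(fit, "variant") <- config$variant
  fit
}
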