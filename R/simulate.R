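#' Configuration for the paired multi-omics simulator
#'
#' The generator emulates the structure the integration network is designed
#' for: a shared low-dimensional cell state observed through modalities of
#' very different width and noise character — e.g. a high-dimensional,
#' zero-inflated count modality (RNA-like) next to a compact, dense panel
#' (ADT-like). Defaults mirror the desk-scale benchmark conditions used
#' throughout the package: 2,000 cells in 5 clusters observed as a 500-feature
#' count modality with 50% dropout plus a 20-feature count panel without
#' dropout.
#'
#' @param n_cells number of cells.
#' @param n_clusters number of ground-truth cell types (equal proportions).
#' @param latent_dim dimension of the shared latent cell state.
#' @param modality_dims integer vector of per-modality feature counts d_i.
#' @param cluster_separation minimum pairwise distance between cluster centers
#'   in latent units (per-cell latent noise is standard normal, so separation
#'   6 with 10 latent dimensions gives well-separated but overlapping-scale
#'   clusters).
#' @param noise_sd per-modality additive Gaussian noise on the expression
#'   rates (recycled).
#' @param dropout_rate per-modality probability of technical zero-masking
#'   (recycled), each in `[0, 1)`.
#' @param n_batches number of batches (0 or 1 disables batch structure).
#' @param batch_shift_sd sd of the per-batch, per-feature additive shift.
#' @param count_like per-modality flags (recycled): `TRUE` emits non-negative
#'   integer counts via a Poisson draw, `FALSE` continuous values.
#' @param modality_tags per-modality names; defaults to `RNA`, `ADT`, `M3`,
#'   ... by position.
#' @param seed integer seed; every random choice derives from it.
#' @return an object of class `simulation_config`.
#' @export
simulation_config <- function(n_cells = 2000, n_clusters = 5, latent_dim = 10,
                              modality_dims = c(500, 20),
                              cluster_separation = 6,
                              noise_sd = c(0.1, 0.1),
                              dropout_rate = c(0.5, 0), n_batches = 0,
                              batch_shift_sd = 0, count_like = TRUE,
                              modality_tags = NULL, seed = 1) {
  m <- length(modality_dims)
  stopifnot(n_cells >= 1, n_clusters >= 1, latent_dim >= 1, m >= 1,
            all(modality_dims >= 1), cluster_separation > 0,
            n_batches >= 0, batch_shift_sd >= 0)
  noise_sd <- rep_len(noise_sd, m)
  dropout_rate <- rep_len(dropout_rate, m)
  count_like <- rep_len(count_like, m)
  if (any(noise_sd < 0)) stop("noise_sd must be non-negative")
  if (any(dropout_rate < 0 | dropout_rate >= 1))
    stop("dropout_rate must be in [0, 1)")
  if (is.null(modality_tags))
    modality_tags <- c("RNA", "ADT", paste0("M", seq_len(max(0, m - 2)) + 2))[seq_len(m)]
  structure(list(n_cells = as.integer(n_cells),
                 n_clusters = as.integer(n_clusters),
                 latent_dim = as.integer(latent_dim),
                 modality_dims = as.integer(modality_dims),
                 cluster_separation = cluster_separation, noise_sd = noise_sd,
                 dropout_rate = dropout_rate, n_batches = as.integer(n_batches),
                 batch_shift_sd = batch_shift_sd, count_like = count_like,
                 modality_tags = modality_tags, seed = as.integer(seed)),
            class = "simulation_config")
}

softplus <- function(x) {
  # numerically stable log(1 + exp(x))
  pmax(x, 0) + log1p(exp(-abs(x)))
}

# Cluster centers at random directions, rescaled until every pairwise distance
# reaches the requested separation; deterministic given the RNG state.
draw_centers <- function(k, latent_dim, separation) {
  if (k == 1) return(matrix(0, 1, latent_dim))
  scale <- separation
  for (try in 1:100) {
    centers <- matrix(stats::rnorm(k * latent_dim), k, latent_dim) * scale
    if (min(stats::dist(centers)) >= separation) return(centers)
    scale <- scale * 1.25
  }
  stop("could not place cluster centers at the requested separation")
}

#' Simulate a paired multi-omics dataset with known structure
#'
#' Draws cluster centers in a shared latent space, gives each cell a latent
#' state `z = center + N(0, I)`, and observes each modality through its own
#' random linear map followed by a softplus link: `rate = softplus(z A_i)`.
#' Batch shifts (if any) and Gaussian noise perturb the rates; count-like
#' modalities then draw `Poisson(rate)` counts; finally independent Bernoulli
#' dropout zero-masks entries. All randomness derives from `config$seed`, so
#' the same config reproduces the same dataset bit for bit.
#'
#' @param config a [simulation_config()].
#' @return an object of class `SyntheticDataset`: a list with `data` (a
#'   `PairedDataset` carrying labels and batches), `true_labels`,
#'   `true_latent` and `batch_labels` (`NULL` unless `n_batches >= 2`).
#' @export
simulate_multiomics <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  n <- config$n_cells
  k <- config$n_clusters
  centers <- draw_centers(k, config$latent_dim, config$cluster_separation)
  labels_idx <- sample(rep_len(seq_len(k), n))
  z <- centers[labels_idx, , drop = FALSE] +
    matrix(stats::rnorm(n * config$latent_dim), n)
  batch_labels <- NULL
  if (config$n_batches >= 2)
    batch_labels <- sample(rep_len(seq_len(config$n_batches), n))
  cell_ids <- sprintf("cell%04d", seq_len(n))
  modalities <- vector("list", length(config$modality_dims))
  for (i in seq_along(config$modality_dims)) {
    d <- config$modality_dims[i]
    A <- matrix(stats::rnorm(config$latent_dim * d), config$latent_dim, d) /
      sqrt(config$latent_dim)
    rate <- softplus(z %*% A)
    if (!is.null(batch_labels) && config$batch_shift_sd > 0) {
      shifts <- matrix(stats::rnorm(config$n_batches * d,
                                    sd = config$batch_shift_sd),
                       config$n_batches, d)
      rate <- rate + shifts[batch_labels, , drop = FALSE]
    }
    if (config$noise_sd[i] > 0)
      rate <- rate + matrix(stats::rnorm(n * d, sd = config$noise_sd[i]), n)
    rate <- pmax(rate, 0)
    x <- if (config$count_like[i])
      matrix(stats::rpois(n * d, lambda = rate), n)
    else rate
    if (config$dropout_rate[i] > 0) {
      keep <- matrix(stats::runif(n * d) >= config$dropout_rate[i], n)
      x <- x * keep
    }
    modalities[[i]] <- omics_matrix(
      x, cell_ids = cell_ids,
      feature_ids = sprintf("%s_f%04d", config$modality_tags[i], seq_len(d)),
      modality_tag = config$modality_tags[i],
      is_count = config$count_like[i])
  }
  labels <- paste0("type", labels_idx)
  batches <- if (!is.null(batch_labels)) paste0("batch", batch_labels) else NULL
  structure(list(
    data = paired_dataset(modalities, labels = labels, batches = batches),
    true_labels = labels,
    true_latent = z,
    batch_labels = batches,
    config = config), class = "SyntheticDataset")
}

#' @export
print.SyntheticDataset <- function(x, ...) {
  cat(sprintf("SyntheticDataset: %d cells, %d clusters, dims (%s)\n",
              x$config$n_cells, x$config$n_clusters,
              paste(x$config$modality_dims, collapse = ",")))
  invisible(x)
}

#' Write a synthetic dataset as an on-disk fixture
#'
#' Emits each count-like modality as Matrix Market (features x cells, with
#' barcode/feature sidecars) and each continuous modality as CSV, plus
#' `labels.tsv` and `batches.tsv` (two-column barcode/value), the true latent
#' coordinates as `truth_latent.csv`, and a `manifest.json` describing the
#' layout and the generating configuration. Everything round-trips through
#' [read_matrix()] / [read_fixture()].
#'
#' @param ds a `SyntheticDataset`.
#' @param dir output directory (created if missing).
#' @return the manifest path, invisibly.
#' @export
write_fixture <- function(ds, dir) {
  stopifnot(inherits(ds, "SyntheticDataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- list()
  for (mod in ds$data$modalities) {
    tag <- mod$modality_tag
    if (mod$is_count) {
      # MTX goes out features x cells, the common single-cell convention;
      # the orientation is recorded in the manifest
      path <- file.path(dir, paste0(tag, ".mtx"))
      write_matrix(mod, path, fmt = "mtx")
      files[[tag]] <- list(file = basename(path), fmt = "mtx",
                           orientation = "features_by_cells",
                           is_count = TRUE)
    } else {
      path <- file.path(dir, paste0(tag, ".csv"))
      write_matrix(mod, path, fmt = "csv")
      files[[tag]] <- list(file = basename(path), fmt = "csv",
                           orientation = "cells_by_features",
                           is_count = FALSE)
    }
  }
  ids <- ds$data$modalities[[1]]$cell_ids
  utils::write.table(data.frame(ids, ds$true_labels),
                     file.path(dir, "labels.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  if (!is.null(ds$batch_labels))
    utils::write.table(data.frame(ids, ds$batch_labels),
                       file.path(dir, "batches.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  latent <- as.data.frame(ds$true_latent)
  colnames(latent) <- paste0("latent_", seq_len(ncol(latent)))
  utils::write.csv(cbind(cell_id = ids, latent),
                   file.path(dir, "truth_latent.csv"), row.names = FALSE,
                   quote = FALSE)
  manifest <- list(format = "umint-fixture-v1", modalities = files,
                   labels = "labels.tsv",
                   batches = if (!is.null(ds$batch_labels)) "batches.tsv",
                   truth_latent = "truth_latent.csv",
                   config = unclass(ds$config))
  mpath <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(mpath)
}

#' Read a fixture directory written by [write_fixture()]
#'
#' @param dir fixture directory containing `manifest.json`.
#' @return a `PairedDataset` with labels and batches attached.
#' @export
read_fixture <- function(dir) {
  mpath <- file.path(dir, "manifest.json")
  if (!file.exists(mpath)) stop("no manifest.json in ", dir)
  manifest <- jsonlite::read_json(mpath, simplifyVector = TRUE)
  mods <- lapply(names(manifest$modalities), function(tag) {
    info <- manifest$modalities[[tag]]
    read_matrix(file.path(dir, info$file), fmt = info$fmt,
                orientation = info$orientation, modality_tag = tag,
                is_count = isTRUE(info$is_count))
  })
  labels <- if (!is.null(manifest$labels))
    read_labels(file.path(dir, manifest$labels))
  batches <- if (!is.null(manifest$batches) && !is.na(manifest$batches[1]) &&
                 file.exists(file.path(dir, manifest$batches)))
    read_labels(file.path(dir, manifest$batches))
  align_cells(mods, labels = labels, batches = batches)
}
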