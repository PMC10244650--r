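# Shared helpers: small in-code fixtures and independent metric oracles.

make_counts <- function(n = 4, d = 3, seed = 1, tag = "RNA") {
  set.seed(seed)
  omics_matrix(matrix(rpois(n * d, 3), n, d),
               cell_ids = paste0("c", seq_len(n)),
               feature_ids = paste0("f", seq_len(d)),
               modality_tag = tag, is_count = TRUE)
}

make_continuous <- function(n = 6, d = 4, seed = 1, tag = "ADT") {
  set.seed(seed)
  omics_matrix(matrix(rnorm(n * d), n, d),
               cell_ids = paste0("c", seq_len(n)),
               feature_ids = paste0("g", seq_len(d)),
               modality_tag = tag, is_count = FALSE)
}

# Brute-force pair-counting oracle: enumerates all N(N-1)/2 unordered pairs.
oracle_pair_counts <- function(a, b) {
  n <- length(a)
  tp <- fp <- fn <- tn <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    sa <- a[i] == a[j]
    sb <- b[i] == b[j]
    if (sa && sb) tp <- tp + 1
    else if (sa && !sb) fp <- fp + 1
    else if (!sa && sb) fn <- fn + 1
    else tn <- tn + 1
  }
  list(tp = tp, fp = fp, fn = fn, tn = tn)
}

# ARI from pair counts (an algebraically independent route to the
# contingency-table formula).
oracle_ari <- function(a, b) {
  pc <- oracle_pair_counts(a, b)
  num <- 2 * (pc$tp * pc$tn - pc$fn * pc$fp)
  den <- (pc$tp + pc$fp) * (pc$fp + pc$tn) + (pc$tp + pc$fn) * (pc$fn + pc$tn)
  # den == 0 forces fp == fn == 0, i.e. identical partitions
  if (den == 0) return(1)
  num / den
}

oracle_fmi <- function(a, b) {
  pc <- oracle_pair_counts(a, b)
  if ((pc$tp + pc$fp) == 0 || (pc$tp + pc$fn) == 0) return(0)
  pc$tp / sqrt((pc$tp + pc$fp) * (pc$tp + pc$fn))
}

# Two well-separated Gaussian blobs in `dim` dimensions.
make_blobs <- function(n_per = 20, dim = 3, separation = 50, sd = 1, seed = 1) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n_per * dim, 0, sd), n_per),
             matrix(rnorm(n_per * dim, separation, sd), n_per))
  list(x = x, labels = rep(1:2, each = n_per))
}

# A tiny preprocessed paired dataset ready for training.
make_training_data <- function(n = 120, dims = c(40, 8), clusters = 3,
                               seed = 5) {
  ds <- simulate_multiomics(simulation_config(
    n_cells = n, n_clusters = clusters, modality_dims = dims,
    dropout_rate = c(0.3, 0), seed = seed))
  mods <- list(preprocess_modality(ds$data$modalities[[1]], "rna",
                                   n_hvg = dims[1]),
               preprocess_modality(ds$data$modalities[[2]], "adt"))
  list(data = paired_dataset(mods, labels = ds$true_labels), truth = ds)
}

# Move all biases off the ReLU kinks (finite differences are only meaningful
# where the loss is differentiable).
jitter_biases <- function(model, sd = 0.1, seed = 1) {
  set.seed(seed)
  for (i in seq_along(model$modules))
    for (nm in c("b1", "b3", "b4"))
      model$modules[[i]][[nm]] <- rnorm(length(model$modules[[i]][[nm]]), sd = sd)
  model$b2 <- rnorm(length(model$b2), sd = sd)
  model
}

# Central finite-difference gradient of the training objective for one
# parameter tensor, addressed by module index (0 = shared b2) and name.
numeric_grad <- function(model, xs, module, name, entries, eps = 1e-5) {
  get <- function(m) if (module == 0) m$b2 else m$modules[[module]][[name]]
  set <- function(m, p) {
    if (module == 0) m$b2[] <- p else m$modules[[module]][[name]][] <- p
    m
  }
  p0 <- get(model)
  vapply(entries, function(j) {
    pp <- p0; pp[j] <- pp[j] + eps
    pm <- p0; pm[j] <- pm[j] - eps
    (umint_loss(set(model, pp), xs)$total -
       umint_loss(set(model, pm), xs)$total) / (2 * eps)
  }, numeric(1))
}
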