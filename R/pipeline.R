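pkg_version <- function() as.character(utils::packageVersion("umint"))

write_manifest <- function(out_dir, command, params, inputs = character(),
                           outputs = character()) {
  digest <- function(p) {
    info <- file.info(p)
    if (is.na(info$size)) return(NA_character_)
    if (isTRUE(info$isdir)) {
      inner <- list.files(p, full.names = TRUE)
      inner <- inner[!file.info(inner)$isdir]
      return(paste0("dir:", length(inner)))
    }
    # cheap content fingerprint: size plus checksum of the bytes
    bytes <- readBin(p, "raw", info$size)
    sprintf("%d:%.0f", length(bytes), sum(as.integer(bytes)))
  }
  manifest <- list(command = command, package_version = pkg_version(),
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                   parameters = params,
                   inputs = if (length(inputs))
                     stats::setNames(lapply(inputs, digest), inputs),
                   outputs = as.list(outputs))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(manifest)
}

resolve_dataset <- function(dataset, recipes = NULL, n_hvg = 2000) {
  if (inherits(dataset, "SyntheticDataset")) dataset <- dataset$data
  stopifnot(inherits(dataset, "PairedDataset"))
  if (is.null(recipes)) return(dataset)
  recipes <- rep_len(recipes, length(dataset$modalities))
  mods <- mapply(function(m, r) preprocess_modality(m, recipe = r, n_hvg = n_hvg),
                 dataset$modalities, recipes, SIMPLIFY = FALSE)
  paired_dataset(mods, labels = dataset$labels, batches = dataset$batches)
}

#' Preprocess, train and embed in one step
#'
#' Applies the per-modality preprocessing recipes, trains the modular network,
#' and writes the model archive, the embedding CSV, the per-epoch loss trace
#' and a run manifest into `out_dir`.
#'
#' @param dataset a `PairedDataset` or `SyntheticDataset` (raw or already
#'   preprocessed), or a fixture directory path readable by [read_fixture()].
#' @param config an [umint_config()].
#' @param recipes per-modality preprocessing recipes (`"rna"`, `"adt"`,
#'   `"none"`), recycled; `NULL` uses the data as given.
#' @param n_hvg number of variable features kept by the `"rna"` recipe.
#' @param out_dir output directory; `NULL` skips writing.
#' @return invisibly, a list with the `fit` (an `umint_fit`), the `embedding`,
#'   and the preprocessed `dataset`.
#' @export
run_train <- function(dataset, config = umint_config(), recipes = NULL,
                      n_hvg = 2000, out_dir = NULL) {
  input_path <- if (is.character(dataset)) dataset else character()
  if (is.character(dataset)) dataset <- read_fixture(dataset)
  data <- resolve_dataset(dataset, recipes, n_hvg)
  fit <- train_umint(data, config)
  embedding <- umint_encode(fit$model, data)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    save_umint(fit$model, file.path(out_dir, "model.json"))
    write_embedding(embedding, file.path(out_dir, "embedding.csv"))
    utils::write.csv(fit$history, file.path(out_dir, "loss_trace.csv"),
                     row.names = FALSE)
    write_manifest(out_dir, "train",
                   params = c(unclass(fit$model$config),
                              list(recipes = recipes, n_hvg = n_hvg)),
                   inputs = input_path,
                   outputs = c("model.json", "embedding.csv", "loss_trace.csv"))
  }
  invisible(list(fit = fit, embedding = embedding, dataset = data))
}

#' Cluster an embedding and score it
#'
#' Clusters the embedding with both k-means and Ward hierarchical clustering
#' and reports external indices (ARI, FMI, against the supplied labels) and
#' internal indices (silhouette, Davies-Bouldin). Labels are joined by cell id
#' when named, so file order does not matter. If `k` is not given it defaults
#' to the number of distinct labels.
#'
#' @param embedding an `Embedding`, matrix, or path to an embedding CSV.
#' @param labels optional per-cell labels (vector, named vector, or label file
#'   path).
#' @param k number of clusters; required when `labels` is `NULL`.
#' @param seed seed for k-means restarts.
#' @param out optional path for a JSON metrics report.
#' @return a list of per-method metric lists, of class `umint_metrics`.
#' @export
run_evaluate <- function(embedding, labels = NULL, k = NULL, seed = 1,
                         out = NULL) {
  if (is.character(embedding)) embedding <- read_embedding(embedding)
  if (is.matrix(embedding)) embedding <- new_embedding(embedding)
  if (is.character(labels) && length(labels) == 1 && file.exists(labels))
    labels <- read_labels(labels)
  if (!is.null(labels)) {
    if (!is.null(names(labels))) {
      missing <- setdiff(embedding$cell_ids, names(labels))
      if (length(missing))
        stop("labels missing for cells: ",
             paste(utils::head(missing, 5), collapse = ", "))
      labels <- unname(labels[embedding$cell_ids])
    } else if (length(labels) != length(embedding$cell_ids)) {
      stop("unnamed labels must have one entry per embedded cell")
    }
    if (is.null(k)) k <- length(unique(labels))
  }
  if (is.null(k)) stop("supply labels or k")
  res <- list()
  for (method in c("kmeans", "hierarchical")) {
    cl <- cluster_embedding(embedding, k = k, method = method, seed = seed)
    entry <- list(method = method, k = k, seed = seed)
    if (!is.null(labels)) {
      entry$ari <- ari(cl, labels)
      entry$fmi <- fmi(cl, labels)
    }
    entry <- c(entry, tryCatch(internal_indices(embedding, cl),
                               error = function(e)
                                 list(silhouette = NA_real_,
                                      davies_bouldin = NA_real_,
                                      internal_error = conditionMessage(e))))
    res[[method]] <- entry
  }
  res <- structure(res, class = "umint_metrics")
  if (!is.null(out))
    jsonlite::write_json(lapply(unclass(res), identity), out,
                         auto_unbox = TRUE, digits = NA, null = "null")
  res
}

#' @export
print.umint_metrics <- function(x, ...) {
  for (e in x) {
    cat(sprintf("%-12s k=%d", e$method, e$k))
    if (!is.null(e$ari)) cat(sprintf("  ARI %.4f  FMI %.4f", e$ari, e$fmi))
    if (!is.null(e$silhouette) && !is.na(e$silhouette))
      cat(sprintf("  silhouette %.4f  DB %.4f", e$silhouette, e$davies_bouldin))
    cat("\n")
  }
  invisible(x)
}

split_train_test <- function(n, seed, train_frac = 0.8) {
  set.seed(seed)
  idx <- sample.int(n)
  n_train <- max(1L, floor(train_frac * n))
  list(train = sort(idx[seq_len(n_train)]), test = sort(idx[-seq_len(n_train)]))
}

subset_paired <- function(data, idx) {
  mods <- lapply(data$modalities, function(m)
    omics_matrix(m$values[idx, , drop = FALSE], cell_ids = m$cell_ids[idx],
                 feature_ids = m$feature_ids, modality_tag = m$modality_tag,
                 is_count = m$is_count))
  paired_dataset(mods, labels = data$labels[idx], batches = data$batches[idx])
}

#' Compare the modular network against matched dense autoencoder baselines
#'
#' Trains the modular network and the AE, DAE and SAE baselines with identical
#' shared hyperparameters on the same data, repeating over `n_seeds` fresh
#' 80:20 train/test splits. Reconstruction quality (ORS) is scored on held-out
#' test cells; clustering quality (ARI/FMI against the dataset's labels, via
#' k-means on the embedding) on all cells. Per-seed rows, a per-method median
#' row, first-layer parameter counts and per-epoch wall-clock are reported.
#'
#' @param dataset a `PairedDataset` with labels (preprocessed), a
#'   `SyntheticDataset`, or a fixture directory path.
#' @param config an [umint_config()] for the modular network; the baselines
#'   inherit its bottleneck width, beta, epochs, batch size and learning rate,
#'   and pin their hidden width to `sum(hidden_widths)`.
#' @param n_seeds number of train/test repetitions.
#' @param recipes,n_hvg optional preprocessing, as in [run_train()].
#' @param variants which baselines to run alongside the modular network.
#' @param out_dir optional output directory for `comparison.csv` and a
#'   manifest.
#' @return a list of class `umint_comparison` with `results` (one row per
#'   method x seed), `medians`, and `parameter_counts`.
#' @export
run_compare <- function(dataset, config = umint_config(), n_seeds = 3,
                        recipes = NULL, n_hvg = 2000,
                        variants = c("AE", "DAE", "SAE"), out_dir = NULL) {
  input_path <- if (is.character(dataset)) dataset else character()
  if (is.character(dataset)) dataset <- read_fixture(dataset)
  data <- resolve_dataset(dataset, recipes, n_hvg)
  if (is.null(data$labels)) stop("run_compare needs per-cell labels")
  dims <- vapply(data$modalities, function(m) ncol(m$values), integer(1))
  cfg0 <- resolve_config(dims, config)
  pc <- parameter_reduction(dims, cfg0$hidden_widths)
  k_clusters <- length(unique(data$labels))
  n <- n_cells(data)
  rows <- list()
  for (s in seq_len(n_seeds)) {
    seed_s <- cfg0$seed + s - 1L
    sp <- split_train_test(n, seed = seed_s)
    train_data <- subset_paired(data, sp$train)
    test_data <- subset_paired(data, sp$test)
    run_one <- function(method) {
      t0 <- proc.time()[["elapsed"]]
      if (method == "UMINT") {
        cfg <- cfg0
        cfg$seed <- seed_s
        fit <- train_umint(train_data, cfg)
        recon_test <- umint_encode(fit$model, test_data,
                                   with_activations = TRUE)$reconstructions
        score <- ors(test_data, recon_test, seed = seed_s)
        emb <- umint_encode(fit$model, data)
      } else {
        bcfg <- baseline_config(variant = method,
                                hidden_width = sum(cfg0$hidden_widths),
                                bottleneck_width = cfg0$bottleneck_width,
                                beta = cfg0$beta, epochs = cfg0$epochs,
                                batch_size = cfg0$batch_size,
                                learning_rate = cfg0$learning_rate,
                                seed = seed_s)
        stacked_train <- stack_modalities(train_data)
        fit <- train_baseline(stacked_train, bcfg)
        # score reconstructions per original modality by splitting the
        # stacked reconstruction back into blocks
        stacked_test <- stack_modalities(test_data)
        recon <- umint_encode(fit$model, stacked_test,
                              with_activations = TRUE)$reconstructions[[1]]
        offsets <- cumsum(c(0, dims))
        recon_split <- lapply(seq_along(dims), function(i)
          recon[, (offsets[i] + 1):offsets[i + 1], drop = FALSE])
        score <- ors(test_data, recon_split, seed = seed_s)
        emb <- umint_encode(fit$model, stack_modalities(data))
      }
      elapsed <- proc.time()[["elapsed"]] - t0
      cl <- cluster_embedding(emb, k = k_clusters, method = "kmeans",
                              seed = seed_s)
      data.frame(method = method, seed = seed_s, ors = score$ors,
                 ari = ari(cl, data$labels), fmi = fmi(cl, data$labels),
                 first_layer_weights = if (method == "UMINT") pc$tp_umint
                 else pc$tp_ae,
                 seconds_per_epoch = elapsed / cfg0$epochs,
                 final_loss = fit$history$total[nrow(fit$history)])
    }
    for (method in c("UMINT", variants)) rows[[length(rows) + 1]] <- run_one(method)
  }
  results <- do.call(rbind, rows)
  medians <- do.call(rbind, lapply(split(results, results$method), function(df)
    data.frame(method = df$method[1], seed = NA_integer_,
               ors = stats::median(df$ors), ari = stats::median(df$ari),
               fmi = stats::median(df$fmi),
               first_layer_weights = df$first_layer_weights[1],
               seconds_per_epoch = stats::median(df$seconds_per_epoch),
               final_loss = stats::median(df$final_loss))))
  rownames(medians) <- NULL
  out <- structure(list(results = results, medians = medians,
                        parameter_counts = pc), class = "umint_comparison")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(rbind(results, medians),
                     file.path(out_dir, "comparison.csv"), row.names = FALSE)
    write_manifest(out_dir, "compare",
                   params = c(unclass(cfg0), list(n_seeds = n_seeds)),
                   inputs = input_path, outputs = "comparison.csv")
  }
  out
}

#' @export
print.umint_comparison <- function(x, ...) {
  cat("median over seeds:\n")
  print(x$medians, row.names = FALSE)
  print(x$parameter_counts)
  invisible(x)
}
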