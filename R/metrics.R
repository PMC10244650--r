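#' Contingency table between two labelings
#'
#' Cross-tabulates two per-cell category vectors into counts `c_ij` with row
#' sums `p_i`, column sums `q_j` and total `N` — the quantities from which the
#' adjusted Rand and Fowlkes-Mallows indices are computed.
#'
#' @param labels_a,labels_b per-cell category vectors of equal length.
#' @return a list of class `contingency_table` with `counts`, `row_sums`,
#'   `col_sums` and `n`.
#' @export
contingency_table <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b))
    stop("labelings have different lengths")
  if (length(labels_a) < 2) stop("need at least 2 observations")
  counts <- unclass(table(as.character(labels_a), as.character(labels_b)))
  structure(list(counts = counts, row_sums = rowSums(counts),
                 col_sums = colSums(counts), n = sum(counts)),
            class = "contingency_table")
}

choose2 <- function(x) x * (x - 1) / 2

#' Pair counts between two labelings
#'
#' Counts unordered cell pairs that are co-clustered in both labelings (TP),
#' only in the first (FP), only in the second (FN), or in neither (TN),
#' derived from the contingency table: `TP = sum choose(c_ij, 2)`,
#' `TP + FP = sum choose(p_i, 2)`, `TP + FN = sum choose(q_j, 2)`.
#'
#' @inheritParams contingency_table
#' @return a list with `tp`, `fp`, `fn`, `tn`; they sum to `N (N - 1) / 2`.
#' @export
pair_counts <- function(labels_a, labels_b) {
  ct <- contingency_table(labels_a, labels_b)
  tp <- sum(choose2(ct$counts))
  fp <- sum(choose2(ct$row_sums)) - tp
  fn <- sum(choose2(ct$col_sums)) - tp
  tn <- choose2(ct$n) - tp - fp - fn
  list(tp = tp, fp = fp, fn = fn, tn = tn)
}

#' Adjusted Rand Index
#'
#' Chance-corrected agreement between two partitions:
#' `(index - expected) / (max - expected)` with `index = sum choose(c_ij, 2)`,
#' `expected = sum choose(p_i, 2) * sum choose(q_j, 2) / choose(N, 2)` and
#' `max = (sum choose(p_i, 2) + sum choose(q_j, 2)) / 2`. Equals 1 for
#' identical partitions and concentrates near 0 for random ones. In the
#' degenerate case where the denominator vanishes (both partitions trivial —
#' all singletons or a single cluster), returns 1 if the partitions are
#' identical and 0 otherwise.
#'
#' @inheritParams contingency_table
#' @return a number, at most 1.
#' @export
ari <- function(labels_a, labels_b) {
  ct <- contingency_table(labels_a, labels_b)
  index <- sum(choose2(ct$counts))
  pa <- sum(choose2(ct$row_sums))
  pb <- sum(choose2(ct$col_sums))
  expected <- pa * pb / choose2(ct$n)
  maximum <- (pa + pb) / 2
  if (abs(maximum - expected) < 1e-12) {
    same <- ari_partitions_equal(labels_a, labels_b)
    return(if (same) 1 else 0)
  }
  (index - expected) / (maximum - expected)
}

ari_partitions_equal <- function(labels_a, labels_b) {
  ct <- contingency_table(labels_a, labels_b)
  # identical partitions up to renaming: one nonzero cell per row and column
  all(rowSums(ct$counts > 0) == 1) && all(colSums(ct$counts > 0) == 1)
}

#' Fowlkes-Mallows Index
#'
#' Geometric mean of pairwise precision and recall:
#' `TP / sqrt((TP + FP) (TP + FN))`, in `[0, 1]`; returns 0 when either
#' marginal pair count is zero (a partition into singletons).
#'
#' @inheritParams contingency_table
#' @return a number in `[0, 1]`.
#' @export
fmi <- function(labels_a, labels_b) {
  ct <- contingency_table(labels_a, labels_b)
  tp <- sum(choose2(ct$counts))
  tp_fp <- sum(choose2(ct$row_sums))
  tp_fn <- sum(choose2(ct$col_sums))
  if (tp_fp == 0 || tp_fn == 0) return(0)
  tp / sqrt(tp_fp * tp_fn)
}

# k-means++ seeding: first center uniform, then proportional to squared
# distance to the nearest chosen center.
kmeanspp_init <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  idx <- sample.int(n, 1)
  centers[1, ] <- x[idx, ]
  if (k > 1) {
    d2 <- rowSums(sweep(x, 2, centers[1, ])^2)
    for (j in 2:k) {
      prob <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
      idx <- sample.int(n, 1, prob = prob)
      centers[j, ] <- x[idx, ]
      d2 <- pmin(d2, rowSums(sweep(x, 2, centers[j, ])^2))
    }
  }
  centers
}

#' Cluster an embedding
#'
#' `"kmeans"`: k-means with seeded k-means++ initialization, best of
#' `nstart` restarts by total within-cluster sum of squares. `"hierarchical"`:
#' agglomerative clustering with Ward linkage on Euclidean distances, cut at
#' `k` clusters (deterministic).
#'
#' @param embedding an `Embedding` or numeric matrix (cells x dimensions).
#' @param k number of clusters, at most the number of cells.
#' @param method `"kmeans"` or `"hierarchical"`.
#' @param seed seed for the k-means restarts.
#' @param nstart number of k-means restarts.
#' @param linkage hierarchical linkage passed to [stats::hclust()]
#'   (`"ward.D2"` is Ward's method on Euclidean distances).
#' @return integer vector of per-cell cluster labels in `1..k`.
#' @export
cluster_embedding <- function(embedding, k, method = c("kmeans", "hierarchical"),
                              seed = 1, nstart = 10, linkage = "ward.D2") {
  method <- match.arg(method)
  x <- if (inherits(embedding, "Embedding")) embedding$values else as.matrix(embedding)
  if (k > nrow(x)) stop("k exceeds the number of cells")
  if (k == 1) return(rep(1L, nrow(x)))
  if (method == "hierarchical") {
    hc <- stats::hclust(stats::dist(x), method = linkage)
    return(as.integer(stats::cutree(hc, k = k)))
  }
  set.seed(seed)
  best <- NULL
  for (r in seq_len(nstart)) {
    centers <- kmeanspp_init(x, k)
    km <- suppressWarnings(stats::kmeans(x, centers = centers,
                                         iter.max = 100, algorithm = "Lloyd"))
    if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
  }
  as.integer(best$cluster)
}

#' Distance-correlation fidelity of one reconstruction
#'
#' Pearson correlation between the condensed Euclidean pairwise-distance
#' vectors of the original modality and its reconstruction, computed on a
#' seeded subsample of at most `max_cells` cells. Equals 1 when reconstruction
#' preserves all between-cell geometry (including under any global linear
#' rescaling).
#'
#' @param original an `OmicsMatrix` or matrix (cells x features).
#' @param reconstructed matrix of the same shape.
#' @param max_cells cap on the number of cells entering the distance
#'   computation.
#' @param seed subsampling seed.
#' @return a correlation in `[-1, 1]`.
#' @export
reconstruction_rho <- function(original, reconstructed, max_cells = 1000,
                               seed = 1) {
  x <- if (inherits(original, "OmicsMatrix")) as_dense(original) else as.matrix(original)
  y <- if (inherits(reconstructed, "OmicsMatrix")) as_dense(reconstructed) else as.matrix(reconstructed)
  if (!all(dim(x) == dim(y))) stop("original and reconstruction shapes differ")
  if (nrow(x) < 3) stop("need at least 3 cells")
  if (nrow(x) > max_cells) {
    set.seed(seed)
    idx <- sort(sample.int(nrow(x), max_cells))
    x <- x[idx, , drop = FALSE]
    y <- y[idx, , drop = FALSE]
  }
  dx <- as.numeric(stats::dist(x))
  dy <- as.numeric(stats::dist(y))
  if (stats::sd(dx) == 0 || stats::sd(dy) == 0)
    stop("degenerate distance vector (constant data or constant reconstruction)")
  stats::cor(dx, dy)
}

#' Overall reconstruction score
#'
#' Mean over modalities of the per-modality distance correlations
#' [reconstruction_rho()]; a single scalar summarizing how faithfully a model
#' reconstructs the geometry of every input modality.
#'
#' @param originals a `PairedDataset` or list of matrices/`OmicsMatrix`.
#' @param reconstructions list of reconstruction matrices, one per modality.
#' @param max_cells,seed forwarded to [reconstruction_rho()].
#' @return a list of class `reconstruction_score` with per-modality `rho` and
#'   their mean `ors`.
#' @export
ors <- function(originals, reconstructions, max_cells = 1000, seed = 1) {
  xs <- as_matrix_list(originals)
  if (length(xs) != length(reconstructions))
    stop("need one reconstruction per modality")
  rho <- vapply(seq_along(xs), function(i)
    reconstruction_rho(xs[[i]], reconstructions[[i]], max_cells = max_cells,
                       seed = seed), numeric(1))
  structure(list(rho = rho, ors = mean(rho)), class = "reconstruction_score")
}

#' @export
print.reconstruction_score <- function(x, ...) {
  cat(sprintf("ORS %.4f (rho: %s)\n", x$ors,
              paste(sprintf("%.4f", x$rho), collapse = ", ")))
  invisible(x)
}

#' Internal cluster validity indices
#'
#' Mean silhouette width (Euclidean) and the Davies-Bouldin index, where each
#' cluster's scatter is the mean Euclidean distance of its cells to the
#' cluster centroid and DB is the mean over clusters of the worst
#' `(s_i + s_j) / d(centroid_i, centroid_j)` ratio. Two clusters sharing a
#' centroid give an infinite DB (returned as `Inf`).
#'
#' @param embedding an `Embedding` or numeric matrix.
#' @param labels per-cell cluster labels with at least 2 distinct values.
#' @return a list with `silhouette` and `davies_bouldin`.
#' @export
internal_indices <- function(embedding, labels) {
  x <- if (inherits(embedding, "Embedding")) embedding$values else as.matrix(embedding)
  labels <- as.character(labels)
  if (length(labels) != nrow(x)) stop("labels length must match cell count")
  cl <- unique(labels)
  if (length(cl) < 2)
    stop("internal indices are undefined for a single cluster")
  if (nrow(x) < 3) stop("need at least 3 cells")
  ids <- as.integer(factor(labels, levels = cl))
  sil <- mean(cluster::silhouette(ids, stats::dist(x))[, "sil_width"])
  centroids <- do.call(rbind, lapply(seq_along(cl), function(i)
    colMeans(x[ids == i, , drop = FALSE])))
  scatter <- vapply(seq_along(cl), function(i) {
    pts <- x[ids == i, , drop = FALSE]
    mean(sqrt(rowSums(sweep(pts, 2, centroids[i, ])^2)))
  }, numeric(1))
  k <- length(cl)
  db_terms <- vapply(seq_len(k), function(i) {
    ratios <- vapply(setdiff(seq_len(k), i), function(j) {
      d <- sqrt(sum((centroids[i, ] - centroids[j, ])^2))
      if (d == 0) Inf else (scatter[i] + scatter[j]) / d
    }, numeric(1))
    max(ratios)
  }, numeric(1))
  list(silhouette = sil, davies_bouldin = mean(db_terms))
}
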