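#' Library-size normalize and log-transform RNA counts
#'
#' Scales each cell so its counts sum to `target_sum` (10,000 by default),
#' then applies `log(1 + value)` elementwise — the standard log-normalization
#' for scRNA-seq count data.
#'
#' @param x an `OmicsMatrix` of raw counts.
#' @param target_sum per-cell total after scaling.
#' @return an `OmicsMatrix` with `is_count = FALSE`.
#' @export
normalize_rna <- function(x, target_sum = 10000) {
  stopifnot(inherits(x, "OmicsMatrix"))
  if (!x$is_count) stop("normalize_rna expects raw counts (is_count = TRUE)")
  if (target_sum <= 0) stop("target_sum must be positive")
  m <- as_dense(x)
  totals <- rowSums(m)
  if (any(totals == 0))
    stop("cells with zero total count (filter first): ",
         paste(utils::head(x$cell_ids[totals == 0], 5), collapse = ", "))
  m <- log1p(m * (target_sum / totals))
  omics_matrix(m, cell_ids = x$cell_ids, feature_ids = x$feature_ids,
               modality_tag = x$modality_tag, is_count = FALSE)
}

#' Centered log-ratio transform
#'
#' The per-cell compositional transform conventionally applied to
#' antibody-derived tag (ADT) counts:
#' `y_f = log(x_f + pseudocount) - mean_f log(x_f + pseudocount)`.
#' With `pseudocount = 0` this is the classical CLR and each transformed cell
#' sums to exactly zero; the default pseudocount of 1 tolerates zeros.
#'
#' @param x an `OmicsMatrix` with non-negative values.
#' @param pseudocount non-negative offset added before taking logs.
#' @return an `OmicsMatrix` with `is_count = FALSE`.
#' @export
clr_transform <- function(x, pseudocount = 1) {
  stopifnot(inherits(x, "OmicsMatrix"))
  if (pseudocount < 0) stop("pseudocount must be non-negative")
  m <- as_dense(x)
  if (min(m) < 0) stop("clr_transform expects non-negative values")
  if (pseudocount == 0 && any(m == 0))
    stop("pseudocount 0 with zero entries: log(0) undefined")
  lm <- log(m + pseudocount)
  lm <- lm - rowMeans(lm)
  omics_matrix(lm, cell_ids = x$cell_ids, feature_ids = x$feature_ids,
               modality_tag = x$modality_tag, is_count = FALSE)
}

#' Select highly variable features
#'
#' Keeps the `n_top` features with the highest variance of the (already
#' log-normalized) values, ordered by descending variance with ties broken by
#' original feature order. Variance here is the usual unbiased sample
#' variance; only the ranking matters.
#'
#' @param x an `OmicsMatrix` of transformed values.
#' @param n_top number of features to keep.
#' @return an `OmicsMatrix` restricted and reordered to the selected features.
#' @export
select_hvg <- function(x, n_top = 2000) {
  stopifnot(inherits(x, "OmicsMatrix"))
  d <- ncol(x$values)
  if (n_top > d) stop(sprintf("n_top (%d) exceeds feature count (%d)", n_top, d))
  m <- as_dense(x)
  v <- apply(m, 2, stats::var)
  ord <- order(-v, seq_along(v))[seq_len(n_top)]
  omics_matrix(x$values[, ord, drop = FALSE], cell_ids = x$cell_ids,
               feature_ids = x$feature_ids[ord], modality_tag = x$modality_tag,
               is_count = x$is_count)
}

#' Center, scale and clip features
#'
#' Z-scores every feature using the population (1/n) standard deviation,
#' maps zero-variance features to all-zeros, and clips the result to
#' `[-clip, clip]` — mirroring the default linear scaling step of standard
#' single-cell toolkits.
#'
#' @param x an `OmicsMatrix` of transformed values (not raw counts).
#' @param clip symmetric clipping bound.
#' @return an `OmicsMatrix` of scaled values.
#' @export
scale_features <- function(x, clip = 10) {
  stopifnot(inherits(x, "OmicsMatrix"))
  if (x$is_count) stop("scale_features expects transformed values, not raw counts")
  if (clip <= 0) stop("clip must be positive")
  m <- as_dense(x)
  n <- nrow(m)
  mu <- colMeans(m)
  sd_pop <- sqrt(colMeans(m^2) - mu^2)
  m <- sweep(m, 2, mu)
  nz <- sd_pop > 0
  m[, nz] <- sweep(m[, nz, drop = FALSE], 2, sd_pop[nz], "/")
  m[, !nz] <- 0
  m[m > clip] <- clip
  m[m < -clip] <- -clip
  omics_matrix(m, cell_ids = x$cell_ids, feature_ids = x$feature_ids,
               modality_tag = x$modality_tag, is_count = FALSE)
}

#' Apply a named preprocessing recipe to one modality
#'
#' `"rna"`: library-size normalization to `target_sum`, log transform,
#' highly-variable-feature selection (capped at the feature count), scaling.
#' `"adt"`: centered log-ratio transform, scaling. `"none"`: passthrough.
#'
#' @param x an `OmicsMatrix`.
#' @param recipe one of `"rna"`, `"adt"`, `"none"`.
#' @param n_hvg number of variable features kept by the `"rna"` recipe.
#' @param target_sum,pseudocount,clip forwarded to the underlying steps.
#' @return a preprocessed `OmicsMatrix`.
#' @export
preprocess_modality <- function(x, recipe = c("rna", "adt", "none"),
                                n_hvg = 2000, target_sum = 10000,
                                pseudocount = 1, clip = 10) {
  recipe <- match.arg(recipe)
  switch(recipe,
         rna = {
           y <- normalize_rna(x, target_sum = target_sum)
           y <- select_hvg(y, n_top = min(n_hvg, ncol(y$values)))
           scale_features(y, clip = clip)
         },
         adt = scale_features(clr_transform(x, pseudocount = pseudocount),
                              clip = clip),
         none = x)
}
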