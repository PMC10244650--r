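#' Construct an OmicsMatrix
#'
#' An `OmicsMatrix` is the basic data container of the package: one modality's
#' measurements as a cells x features matrix, together with cell barcodes,
#' feature identifiers, a modality tag (e.g. `"RNA"`, `"ADT"`, `"ATAC"`), and
#' a flag recording whether the values are still raw counts.
#'
#' @param values numeric matrix (dense `matrix` or sparse `Matrix`), cells in
#'   rows and features in columns.
#' @param cell_ids character vector of unique cell barcodes; defaults to
#'   `rownames(values)`.
#' @param feature_ids character vector of unique feature names; defaults to
#'   `colnames(values)`.
#' @param modality_tag single string naming the modality.
#' @param is_count logical; `TRUE` if `values` are raw (non-negative) counts.
#'
#' @return an object of class `OmicsMatrix`.
#' @export
omics_matrix <- function(values, cell_ids = rownames(values),
                         feature_ids = colnames(values),
                         modality_tag = "RNA", is_count = TRUE) {
  if (!(is.matrix(values) || methods::is(values, "Matrix")))
    stop("`values` must be a matrix or Matrix")
  if (is.null(cell_ids))
    cell_ids <- paste0("cell", seq_len(nrow(values)))
  if (is.null(feature_ids))
    feature_ids <- paste0("feature", seq_len(ncol(values)))
  cell_ids <- as.character(cell_ids)
  feature_ids <- as.character(feature_ids)
  if (length(cell_ids) != nrow(values))
    stop("length(cell_ids) must equal nrow(values)")
  if (length(feature_ids) != ncol(values))
    stop("length(feature_ids) must equal ncol(values)")
  dup <- unique(cell_ids[duplicated(cell_ids)])
  if (length(dup))
    stop("duplicate cell ids: ", paste(utils::head(dup, 5), collapse = ", "))
  dup <- unique(feature_ids[duplicated(feature_ids)])
  if (length(dup))
    stop("duplicate feature ids: ", paste(utils::head(dup, 5), collapse = ", "))
  if (isTRUE(is_count) && min(values) < 0)
    stop("is_count = TRUE but matrix contains negative entries")
  rownames(values) <- cell_ids
  colnames(values) <- feature_ids
  structure(
    list(values = values, cell_ids = cell_ids, feature_ids = feature_ids,
         modality_tag = as.character(modality_tag), is_count = isTRUE(is_count)),
    class = "OmicsMatrix")
}

#' @export
dim.OmicsMatrix <- function(x) dim(x$values)

#' @export
print.OmicsMatrix <- function(x, ...) {
  cat(sprintf("OmicsMatrix <%s>: %d cells x %d features (%s, %s)\n",
              x$modality_tag, nrow(x$values), ncol(x$values),
              if (x$is_count) "counts" else "transformed",
              if (methods::is(x$values, "sparseMatrix")) "sparse" else "dense"))
  invisible(x)
}

#' Dense numeric values of an OmicsMatrix
#'
#' @param x an `OmicsMatrix`.
#' @return a base dense matrix (cells x features).
#' @export
as_dense <- function(x) {
  stopifnot(inherits(x, "OmicsMatrix"))
  as.matrix(x$values)
}

#' Construct a PairedDataset
#'
#' Bundles several modalities measured on the same cells, in the same order,
#' with optional per-cell type labels and batch labels.
#'
#' @param modalities list of `OmicsMatrix` objects sharing identical
#'   `cell_ids` in identical order.
#' @param labels optional character vector of per-cell type labels.
#' @param batches optional character vector of per-cell batch labels.
#'
#' @return an object of class `PairedDataset`.
#' @export
paired_dataset <- function(modalities, labels = NULL, batches = NULL) {
  if (inherits(modalities, "OmicsMatrix")) modalities <- list(modalities)
  if (!length(modalities)) stop("need at least one modality")
  if (!all(vapply(modalities, inherits, logical(1), "OmicsMatrix")))
    stop("all modalities must be OmicsMatrix objects")
  ids <- modalities[[1]]$cell_ids
  for (m in modalities[-1])
    if (!identical(m$cell_ids, ids))
      stop("modalities do not share identical cell ids in identical order; ",
           "use align_cells() first")
  n <- length(ids)
  if (!is.null(labels)) {
    labels <- as.character(labels)
    if (length(labels) != n) stop("labels must have one entry per cell")
  }
  if (!is.null(batches)) {
    batches <- as.character(batches)
    if (length(batches) != n) stop("batches must have one entry per cell")
  }
  names(modalities) <- vapply(modalities, `[[`, character(1), "modality_tag")
  structure(list(modalities = modalities, labels = labels, batches = batches),
            class = "PairedDataset")
}

#' @export
print.PairedDataset <- function(x, ...) {
  cat(sprintf("PairedDataset: %d cells, %d modalities (%s)%s%s\n",
              n_cells(x), length(x$modalities),
              paste(names(x$modalities), collapse = ", "),
              if (!is.null(x$labels)) ", with labels" else "",
              if (!is.null(x$batches)) ", with batches" else ""))
  invisible(x)
}

#' Number of cells in a PairedDataset
#' @param data a `PairedDataset`.
#' @return integer cell count.
#' @export
n_cells <- function(data) {
  stopifnot(inherits(data, "PairedDataset"))
  length(data$modalities[[1]]$cell_ids)
}

#' Align modalities on their common cells
#'
#' Restricts every modality to the intersection of cell barcodes and reorders
#' all of them to one canonical order (the sorted intersection), so that row i
#' refers to the same cell in every modality. The number of cells dropped per
#' modality is stored in the `"dropped"` attribute and reported via `message()`.
#'
#' @param modalities list of `OmicsMatrix` objects.
#' @param labels optional labels, either unnamed (aligned to the first
#'   modality's cells) or named by barcode.
#' @param batches optional batch labels, same conventions as `labels`.
#'
#' @return a `PairedDataset` over the sorted common cells.
#' @export
align_cells <- function(modalities, labels = NULL, batches = NULL) {
  if (inherits(modalities, "OmicsMatrix")) modalities <- list(modalities)
  if (!length(modalities)) stop("need at least one modality")
  common <- Reduce(intersect, lapply(modalities, `[[`, "cell_ids"))
  if (!length(common)) stop("no cells shared across all modalities")
  common <- sort(common)
  dropped <- vapply(modalities, function(m) length(m$cell_ids) - length(common),
                    integer(1))
  names(dropped) <- vapply(modalities, `[[`, character(1), "modality_tag")
  if (any(dropped > 0))
    message("align_cells: dropped ",
            paste(sprintf("%d from %s", dropped[dropped > 0],
                          names(dropped)[dropped > 0]), collapse = ", "))
  aligned <- lapply(modalities, function(m) {
    idx <- match(common, m$cell_ids)
    omics_matrix(m$values[idx, , drop = FALSE], cell_ids = common,
                 feature_ids = m$feature_ids, modality_tag = m$modality_tag,
                 is_count = m$is_count)
  })
  pick <- function(v) {
    if (is.null(v)) return(NULL)
    if (!is.null(names(v))) return(as.character(v[common]))
    ref <- modalities[[1]]$cell_ids
    if (length(v) != length(ref))
      stop("unnamed labels/batches must align to the first modality's cells")
    as.character(v[match(common, ref)])
  }
  out <- paired_dataset(aligned, labels = pick(labels), batches = pick(batches))
  attr(out, "dropped") <- dropped
  out
}
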