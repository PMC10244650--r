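#' Read one modality from disk
#'
#' Reads a count/expression matrix from Matrix Market (with barcode and
#' feature sidecar files) or delimited text, and returns it in the package's
#' internal cells x features orientation regardless of the on-disk layout.
#' Sparse inputs stay sparse.
#'
#' For `fmt = "mtx"` the sidecars default to `<stem>_barcodes.tsv` /
#' `<stem>_features.tsv` next to the matrix (falling back to plain
#' `barcodes.tsv` / `features.tsv` in the same directory). For CSV/TSV the
#' first column must hold row identifiers and the header row column
#' identifiers.
#'
#' @param path path to the matrix file.
#' @param fmt one of `"mtx"`, `"csv"`, `"tsv"`; `"auto"` guesses from the
#'   file extension.
#' @param orientation `"cells_by_features"` or `"features_by_cells"`; how the
#'   file is laid out on disk.
#' @param modality_tag modality label for the resulting `OmicsMatrix`.
#' @param is_count whether the stored values are raw counts.
#' @param barcodes,features explicit sidecar paths for MTX input (optional).
#'
#' @return an `OmicsMatrix` (cells x features).
#' @export
read_matrix <- function(path, fmt = c("auto", "mtx", "csv", "tsv"),
                        orientation = c("cells_by_features", "features_by_cells"),
                        modality_tag = "RNA", is_count = TRUE,
                        barcodes = NULL, features = NULL) {
  fmt <- match.arg(fmt)
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("file not found: ", path)
  if (fmt == "auto") {
    ext <- tolower(tools::file_ext(path))
    fmt <- switch(ext, mtx = "mtx", csv = "csv", tsv = "tsv", txt = "tsv",
                  stop("cannot guess format from extension: ", ext))
  }
  if (fmt == "mtx") {
    sidecar <- function(given, suffix) {
      if (!is.null(given)) return(given)
      stem <- sub("\\.mtx$", "", path)
      cand <- c(paste0(stem, "_", suffix), file.path(dirname(path), suffix))
      hit <- cand[file.exists(cand)]
      if (!length(hit)) stop("missing sidecar for ", path, ": ", suffix)
      hit[1]
    }
    bc <- readLines(sidecar(barcodes, "barcodes.tsv"))
    ft_raw <- utils::read.delim(sidecar(features, "features.tsv"),
                                header = FALSE, colClasses = "character")
    ft <- ft_raw[[1]]
    m <- tryCatch(Matrix::readMM(path),
                  error = function(e) stop("malformed MTX file ", path, ": ",
                                           conditionMessage(e)))
    m <- methods::as(m, "CsparseMatrix")
    if (orientation == "features_by_cells") m <- Matrix::t(m)
    if (nrow(m) != length(bc) || ncol(m) != length(ft))
      stop(sprintf(
        "dimension mismatch: matrix is %d x %d (cells x features) but sidecars give %d barcodes, %d features",
        nrow(m), ncol(m), length(bc), length(ft)))
    return(omics_matrix(m, cell_ids = bc, feature_ids = ft,
                        modality_tag = modality_tag, is_count = is_count))
  }
  sep <- if (fmt == "csv") "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1,
                          check.names = FALSE)
  m <- as.matrix(df)
  if (!is.numeric(m)) stop("non-numeric entries in ", path)
  if (orientation == "features_by_cells") m <- t(m)
  omics_matrix(m, modality_tag = modality_tag, is_count = is_count)
}

#' Write an OmicsMatrix to disk
#'
#' CSV/TSV output is cells x features with the barcode as first column
#' (header `""` over the id column, as `read_matrix()` expects). MTX output is
#' written features x cells (the common on-disk convention for single-cell
#' counts) with `<stem>_barcodes.tsv` and `<stem>_features.tsv` sidecars;
#' integer-valued matrices are written with the MTX `integer` field.
#'
#' @param x an `OmicsMatrix`.
#' @param path output file path (`.mtx`, `.csv` or `.tsv`).
#' @param fmt one of `"auto"`, `"mtx"`, `"csv"`, `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(x, path, fmt = c("auto", "mtx", "csv", "tsv")) {
  stopifnot(inherits(x, "OmicsMatrix"))
  fmt <- match.arg(fmt)
  if (fmt == "auto")
    fmt <- switch(tolower(tools::file_ext(path)), mtx = "mtx", csv = "csv",
                  tsv = "tsv", stop("cannot guess format for ", path))
  if (fmt == "mtx") {
    m <- methods::as(methods::as(Matrix::t(Matrix::Matrix(x$values, sparse = TRUE)),
                                 "generalMatrix"), "TsparseMatrix")
    vals <- m@x
    integral <- all(vals == round(vals))
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("%%%%MatrixMarket matrix coordinate %s general",
                       if (integral) "integer" else "real"), con)
    writeLines(sprintf("%d %d %d", nrow(m), ncol(m), length(vals)), con)
    if (length(vals)) {
      body <- if (integral)
        sprintf("%d %d %d", m@i + 1L, m@j + 1L, as.integer(round(vals)))
      else
        sprintf("%d %d %.17g", m@i + 1L, m@j + 1L, vals)
      writeLines(body, con)
    }
    stem <- sub("\\.mtx$", "", path)
    writeLines(x$cell_ids, paste0(stem, "_barcodes.tsv"))
    writeLines(x$feature_ids, paste0(stem, "_features.tsv"))
    return(invisible(path))
  }
  sep <- if (fmt == "csv") "," else "\t"
  df <- as.data.frame(as_dense(x), check.names = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, col.names = NA)
  invisible(path)
}

#' Read per-cell labels or batch assignments
#'
#' Accepts either a single-column headerless file (one value per cell, in
#' barcode order) or a two-column `(barcode, value)` delimited file; the
#' two-column form is returned named by barcode so it can be joined
#' order-independently.
#'
#' @param path label file.
#' @return character vector, named by barcode for two-column input.
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          colClasses = "character", quote = "")
  if (ncol(df) == 1) {
    # maybe comma/space separated single file
    if (any(grepl(",", df[[1]], fixed = TRUE)))
      df <- utils::read.table(path, header = FALSE, sep = ",",
                              colClasses = "character", quote = "")
  }
  if (ncol(df) >= 2) stats::setNames(df[[2]], df[[1]]) else df[[1]]
}

#' Write an embedding as CSV
#'
#' @param embedding an `Embedding` (see [umint_encode()]).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_embedding <- function(embedding, path) {
  stopifnot(inherits(embedding, "Embedding"))
  df <- data.frame(cell_id = embedding$cell_ids, embedding$values,
                   check.names = FALSE)
  colnames(df) <- c("cell_id", paste0("UMINT_", seq_len(ncol(embedding$values))))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an embedding CSV written by [write_embedding()]
#'
#' @param path CSV path with a `cell_id` column followed by embedding columns.
#' @return an `Embedding`.
#' @export
read_embedding <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!"cell_id" %in% colnames(df)) stop("no cell_id column in ", path)
  vals <- as.matrix(df[, setdiff(colnames(df), "cell_id"), drop = FALSE])
  new_embedding(vals, as.character(df$cell_id))
}
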