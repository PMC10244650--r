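#' Trainable parameters between the input and modality-encoding layers
#'
#' The modular architecture connects each modality's input block only to its
#' own encoding module, so the first-layer weight count is
#' `sum(dims * hidden)` rather than the dense `sum(dims) * sum(hidden)`.
#' Biases are excluded by default, matching the closed-form accounting; set
#' `include_bias = TRUE` to add the `sum(hidden)` first-layer bias terms.
#'
#' @param dims integer vector of modality input dimensions d_i.
#' @param hidden integer vector of encoding-module widths n_i.
#' @param include_bias also count bias terms.
#' @return integer weight count.
#' @export
count_parameters_umint <- function(dims, hidden, include_bias = FALSE) {
  check_dims_hidden(dims, hidden)
  sum(dims * hidden) + if (include_bias) sum(hidden) else 0
}

#' Trainable first-layer parameters of the matched dense autoencoder
#'
#' A dense autoencoder over the stacked input has
#' `sum(dims) * sum(hidden)` weights between its input and first hidden layer.
#'
#' @inheritParams count_parameters_umint
#' @return integer weight count.
#' @export
count_parameters_dense <- function(dims, hidden, include_bias = FALSE) {
  check_dims_hidden(dims, hidden)
  sum(dims) * sum(hidden) + if (include_bias) sum(hidden) else 0
}

#' Parameter saving of the modular architecture over a dense autoencoder
#'
#' The per-side reduction is `sum_i d_i * sum_{j != i} n_j`; the mirrored
#' decoder saves the same amount again, so the total saving is twice that.
#' With a single modality the reduction is zero: the modular network then
#' coincides with an ordinary autoencoder.
#'
#' @inheritParams count_parameters_umint
#' @return a list with `tp_umint`, `tp_ae`, `tp_reduction` and
#'   `tp_total_reduction`, of class `umint_parameter_count`.
#' @export
parameter_reduction <- function(dims, hidden) {
  check_dims_hidden(dims, hidden)
  tp_umint <- count_parameters_umint(dims, hidden)
  tp_ae <- count_parameters_dense(dims, hidden)
  tp_reduction <- sum(dims * (sum(hidden) - hidden))
  stopifnot(tp_reduction == tp_ae - tp_umint)
  structure(list(tp_umint = tp_umint, tp_ae = tp_ae,
                 tp_reduction = tp_reduction,
                 tp_total_reduction = 2L * tp_reduction),
            class = "umint_parameter_count")
}

#' @export
print.umint_parameter_count <- function(x, ...) {
  cat(sprintf(
    "first-layer weights: modular %d vs dense %d (reduction %d per side, %d total)\n",
    x$tp_umint, x$tp_ae, x$tp_reduction, x$tp_total_reduction))
  invisible(x)
}

check_dims_hidden <- function(dims, hidden) {
  if (length(dims) != length(hidden))
    stop("dims and hidden must have the same length")
  if (!length(dims)) stop("need at least one modality")
  if (any(dims < 1) || any(hidden < 1))
    stop("dims and hidden must all be positive")
  invisible(TRUE)
}
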