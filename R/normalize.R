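#' Quantile-normalize an expression matrix
#'
#' Classic quantile normalization across arrays: each column's i-th order
#' statistic is replaced by the mean of the i-th order statistics over all
#' columns, then values return to their original row positions; within-column
#' ties receive the mean of the substituted values they span. Afterwards every
#' array shares the same intensity distribution (up to tie averaging), which
#' makes the selected-probe values comparable across arrays. The computation
#' is delegated to `limma::normalizeQuantiles(ties = TRUE)`.
#'
#' Normalization is applied after probe selection, on the probe sets x arrays
#' matrix of selected-probe intensities.
#'
#' @param x A `maxrs_fit` or an expression tibble (`probeset_id` + one column
#'   per array, M >= 2).
#' @return The expression tibble, quantile-normalized (stage `"quantile"`).
#' @export
quantile_normalize <- function(x) {
  expr <- as_expression_tbl(x)
  arrays <- probe_arrays(expr)
  if (length(arrays) < 2) abort_config("quantile normalization needs >= 2 arrays")
  m <- intensity_matrix(expr)
  if (any(!is.finite(m))) abort_config("non-finite expression value")
  nm <- limma::normalizeQuantiles(m, ties = TRUE)
  out <- expr
  out[arrays] <- as.data.frame(nm)
  attr(out, "stage") <- "quantile"
  out
}

#' Log2-transform an expression matrix
#'
#' `value <- log2(max(value, floor))` with a positive floor (default 1) so
#' near-zero intensities cannot blow up to large negative logs. The moderated
#' t-test assumes approximately normal log-scale intensities, so this is the
#' default final step before testing; it is explicit and optional rather than
#' hidden inside the test.
#'
#' @param x A `maxrs_fit` or an expression tibble.
#' @param floor Positive lower bound applied before taking logs.
#' @return The expression tibble on the log2 scale (stage `"log2"`).
#' @export
log2_transform <- function(x, floor = 1) {
  if (!is.numeric(floor) || length(floor) != 1 || floor <= 0) {
    abort_config("log floor must be a single positive number")
  }
  expr <- as_expression_tbl(x)
  arrays <- probe_arrays(expr)
  m <- intensity_matrix(expr)
  out <- expr
  out[arrays] <- as.data.frame(log2(pmax(m, floor)))
  attr(out, "stage") <- "log2"
  out
}
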