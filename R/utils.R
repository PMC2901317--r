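# Fixed leading columns of a probe table; everything after them is an array.
PROBE_FIXED_COLS <- c("spot_id", "probeset_id", "kind")

#' Array identifiers of a probe table or expression matrix
#'
#' A probe table carries the columns `spot_id`, `probeset_id`, `kind` and then
#' one intensity column per array; an expression matrix carries `probeset_id`
#' and then one column per array. This helper returns the array columns, in
#' the (stable) order they appear.
#'
#' @param x A probe table or expression matrix (data frame).
#' @return Character vector of array identifiers.
#' @export
probe_arrays <- function(x) {
  setdiff(names(x), c(PROBE_FIXED_COLS))
}

abort_format <- function(msg) abort(msg, class = "maxrs_format_error")
abort_config <- function(msg) abort(msg, class = "maxrs_config_error")
abort_consistency <- function(msg) abort(msg, class = "maxrs_consistency_error")

# Intensity columns of a probe table / expression tibble as a numeric matrix.
intensity_matrix <- function(x) {
  arr <- probe_arrays(x)
  m <- as.matrix(x[arr])
  storage.mode(m) <- "double"
  m
}

# Accepts a maxrs_fit, a maxrs_filtered, or a plain tibble and returns the
# underlying expression/probe tibble.
as_expression_tbl <- function(x) {
  if (inherits(x, "maxrs_fit")) {
    return(x$expression)
  }
  if (!is.data.frame(x) || !"probeset_id" %in% names(x)) {
    abort_format("expected an expression matrix with a `probeset_id` column")
  }
  x
}
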