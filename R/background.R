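#' Nearest-rank empirical percentile
#'
#' The q-th percentile of `x` as the value at index `ceiling(q * N / 100)` of
#' the sorted sample (nearest-rank definition, no interpolation). This is the
#' order-statistic-exact reading of "the q-th percentile of the background
#' intensity distribution".
#'
#' @param x Numeric vector, length >= 1.
#' @param q Percentile in (0, 100).
#' @return A single number from `x`.
#' @export
quantile_nearest_rank <- function(x, q) {
  if (length(x) < 1) abort_config("empty sample for percentile")
  if (!is.numeric(q) || length(q) != 1 || q <= 0 || q >= 100) {
    abort_config("percentile must lie strictly between 0 and 100")
  }
  sort(x)[max(1L, ceiling(q * length(x) / 100))]
}

#' Estimate per-array background thresholds from no-probe spots
#'
#' The intensities of spots carrying no probe measure the background
#' distribution of each array; the background level is its 95th percentile by
#' default. Thresholds are computed per array, which absorbs array-level
#' brightness differences; with `pooled = TRUE` a single threshold is computed
#' from all background spots of all arrays combined (the two coincide when
#' arrays are homogeneous).
#'
#' @param probes A probe table (see [read_probe_table()]) containing at least
#'   one `background` spot.
#' @param q Background percentile, default 95.
#' @param pooled Pool background spots across arrays into one threshold?
#' @return An object of class `maxrs_background`: list with `q`, `pooled` and
#'   `thresholds` (tibble `array_id`, `threshold`).
#' @seealso [apply_background_filter()]
#' @export
estimate_background <- function(probes, q = 95, pooled = FALSE) {
  validate_probe_table(probes)
  if (!is.numeric(q) || length(q) != 1 || q <= 0 || q >= 100) {
    abort_config("background percentile must lie strictly between 0 and 100")
  }
  bg <- probes[probes$kind == "background", , drop = FALSE]
  if (nrow(bg) == 0) abort_config("no background spots to estimate from")
  arrays <- probe_arrays(probes)
  bgm <- intensity_matrix(bg)
  thr <- if (pooled) {
    rep(quantile_nearest_rank(as.vector(bgm), q), length(arrays))
  } else {
    vapply(seq_along(arrays), function(j) quantile_nearest_rank(bgm[, j], q), 0)
  }
  structure(
    list(
      q = q, pooled = pooled,
      thresholds = tibble::tibble(array_id = arrays, threshold = thr)
    ),
    class = "maxrs_background"
  )
}

#' @export
print.maxrs_background <- function(x, ...) {
  cat(
    "Background model: ", x$q, "th percentile of no-probe spots (",
    if (x$pooled) "pooled" else "per array", ")\n",
    sep = ""
  )
  print(x$thresholds)
  invisible(x)
}

#' @method tidy maxrs_background
#' @export
tidy.maxrs_background <- function(x, ...) x$thresholds

#' Retain probes above background in at least one array
#'
#' A perfect-match probe is kept when its intensity strictly exceeds the
#' background threshold in at least one array (ties at the threshold are not
#' "above" it). Probe sets left with no retained probe drop out of the
#' analysis. Background spots have served their purpose and are removed from
#' the filtered table.
#'
#' @param probes A probe table.
#' @param model A `maxrs_background` from [estimate_background()], computed on
#'   the same arrays.
#' @return An object of class `maxrs_filtered`: list with `probes` (retained
#'   pm rows), `report` (one-row tibble of retention counts) and `background`
#'   (the model used).
#' @export
apply_background_filter <- function(probes, model) {
  validate_probe_table(probes)
  if (!inherits(model, "maxrs_background")) {
    abort_config("`model` must come from estimate_background()")
  }
  arrays <- probe_arrays(probes)
  if (!identical(arrays, model$thresholds$array_id)) {
    abort_consistency("background model was estimated on different arrays")
  }
  pm <- probes[probes$kind == "pm", , drop = FALSE]
  m <- intensity_matrix(pm)
  thr <- model$thresholds$threshold
  above <- m > matrix(thr, nrow(m), ncol(m), byrow = TRUE)
  retained <- rowSums(above) > 0
  sets_all <- unique(pm$probeset_id)
  sets_kept <- unique(pm$probeset_id[retained])
  report <- tibble::tibble(
    n_probes_total = nrow(pm),
    n_probes_retained = sum(retained),
    fraction_probes_retained = sum(retained) / nrow(pm),
    n_probesets_total = length(sets_all),
    n_probesets_retained = length(sets_kept),
    n_probesets_dropped = length(sets_all) - length(sets_kept)
  )
  structure(
    list(
      probes = pm[retained, , drop = FALSE],
      report = report,
      background = model
    ),
    class = "maxrs_filtered"
  )
}

#' @export
print.maxrs_filtered <- function(x, ...) {
  r <- x$report
  cat(sprintf(
    "Background filter: %d/%d probes retained (%.1f%%); %d/%d probe sets keep >=1 probe\n",
    r$n_probes_retained, r$n_probes_total, 100 * r$fraction_probes_retained,
    r$n_probesets_retained, r$n_probesets_total
  ))
  invisible(x)
}

#' @method glance maxrs_filtered
#' @export
glance.maxrs_filtered <- function(x, ...) x$report
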