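#' Rank probes within a probe set, per array
#'
#' Intensities of the probes of one probe set are ranked within each array in
#' increasing order (rank 1 = lowest). Tied intensities receive midranks (the
#' mean of the ranks they span), the standard convention for rank statistics;
#' scanner intensities are continuous so ties are rare in practice.
#'
#' @param m Numeric matrix, probes in rows (P), arrays in columns (M).
#' @return A P x M matrix of ranks; each column sums to P(P+1)/2.
#' @export
rank_within_probeset <- function(m) {
  m <- as.matrix(m)
  if (length(m) == 0) abort_config("empty intensity matrix")
  if (any(!is.finite(m))) abort_config("non-finite intensity")
  r <- apply(m, 2, rank, ties.method = "average")
  matrix(r, nrow = nrow(m), ncol = ncol(m), dimnames = dimnames(m))
}

#' Rank sums across arrays
#'
#' For each probe, the sum of its within-probe-set ranks over all arrays.
#' Conservation: the rank sums of a probe set always total M * P(P+1)/2.
#'
#' @param ranks Rank matrix from [rank_within_probeset()].
#' @return Numeric vector of length P.
#' @export
rank_sums <- function(ranks) {
  rowSums(as.matrix(ranks))
}

#' Select the probe with the maximum rank sum
#'
#' Ties in the rank sum are broken by the highest mean intensity over all
#' arrays; a further exact tie is broken by input order, so selection is
#' deterministic and runs are bit-reproducible.
#'
#' @param rank_sum Rank-sum vector.
#' @param mean_intensity Mean intensity per probe, aligned with `rank_sum`.
#' @param spot_ids Spot identifiers, aligned.
#' @return The selected spot id (length-1 character).
#' @export
select_probe <- function(rank_sum, mean_intensity, spot_ids) {
  stopifnot(
    length(rank_sum) == length(mean_intensity),
    length(rank_sum) == length(spot_ids),
    length(rank_sum) >= 1
  )
  cand <- which(rank_sum == max(rank_sum))
  if (length(cand) > 1) {
    cand <- cand[mean_intensity[cand] == max(mean_intensity[cand])]
  }
  spot_ids[cand[1]]
}

#' Maximum rank sum divided by the number of probes
#'
#' The per-probe-set consistency statistic: `max(rank_sum) / P`. It ranges
#' from 1 to M and equals M exactly when one probe has the (untied) top rank
#' in every one of the M arrays, so its distribution summarises how
#' reproducibly the same probe dominates its probe set across arrays.
#'
#' @param rank_sum Rank-sum vector of one probe set.
#' @param n_probes Number of probes P in the set.
#' @return A single number in `[1, M]`.
#' @export
max_rank_stat <- function(rank_sum, n_probes = length(rank_sum)) {
  stopifnot(n_probes >= 1)
  max(rank_sum) / n_probes
}

#' Friedman rank-consistency test for one probe set
#'
#' Treats the P probes as treatments and the M arrays as blocks. With rank
#' sums R_p, the statistic is
#' `Q = [12 / (M k (k+1)) * sum(R_p^2) - 3 M (k+1)] / C`, k = P, where the
#' tie correction is `C = 1 - sum(t^3 - t) / (M (k^3 - k))` over tie groups of
#' size t within each array. `Q` is referred to the chi-square distribution
#' with k - 1 degrees of freedom (upper tail).
#'
#' Rejection of the Friedman null (exchangeable ranks across probes) is what
#' indicates a reproducible probe ordering across arrays, so a *small* p-value
#' means the probe ranking is consistent. The test needs P >= 2 and M >= 2;
#' otherwise, and when every array is completely tied (C = 0), the result is
#' undefined and returned as `NA` so such sets can be excluded from the
#' consistency fraction.
#'
#' @param ranks Rank matrix (P x M) from [rank_within_probeset()].
#' @return List with elements `Q` and `p` (both `NA` when undefined).
#' @export
friedman_ranks_test <- function(ranks) {
  ranks <- as.matrix(ranks)
  k <- nrow(ranks)
  m <- ncol(ranks)
  if (k < 2 || m < 2) {
    return(list(Q = NA_real_, p = NA_real_))
  }
  tie_sum <- sum(apply(ranks, 2, function(col) {
    tt <- rle(sort(col))$lengths
    sum(tt^3 - tt)
  }))
  correction <- 1 - tie_sum / (m * (k^3 - k))
  if (correction <= 0) {
    return(list(Q = NA_real_, p = NA_real_))
  }
  rs <- rowSums(ranks)
  q_raw <- 12 / (m * k * (k + 1)) * sum(rs^2) - 3 * m * (k + 1)
  q <- max(0, q_raw) / correction
  list(Q = q, p = pchisq(q, df = k - 1, lower.tail = FALSE))
}

#' Run MAXRS probe selection over all probe sets
#'
#' For every probe set of a (background-filtered) probe table: rank the
#' retained probes within each array, sum ranks across arrays, and select the
#' probe with the maximum rank sum (ties broken by mean intensity, then input
#' order). The selected probe's raw intensities become the probe set's
#' expression estimates. Ranking uses each retained probe's intensity in
#' *every* array, including arrays where that probe sits below the background
#' threshold: the filter is "above background in at least one array", and a
#' constant probe count per array is what the rank-sum formula requires.
#'
#' Per-probe-set diagnostics accompany the selection: the maximum-rank-sum
#' statistic ([max_rank_stat()]) and the Friedman rank-consistency test
#' ([friedman_ranks_test()]), which is descriptive only — it never gates
#' selection.
#'
#' @param x A `maxrs_filtered` object from [apply_background_filter()], or a
#'   probe table tibble of pm rows.
#' @return An object of class `maxrs_fit`: list with
#'   \describe{
#'     \item{selection}{tibble with one row per probe set: `probeset_id`,
#'       `selected_spot`, `n_probes`, `rank_sum`, `max_rank_stat`,
#'       `friedman_Q`, `friedman_p`.}
#'     \item{expression}{tibble `probeset_id` x arrays of the selected probes'
#'       raw intensities (stage `"raw"`).}
#'     \item{arrays}{array identifiers, in input order.}
#'   }
#' @export
run_maxrs <- function(x) {
  probes <- if (inherits(x, "maxrs_filtered")) x$probes else x
  if (!is.data.frame(probes) || !all(PROBE_FIXED_COLS %in% names(probes))) {
    abort_format("expected a filtered probe table")
  }
  if ("kind" %in% names(probes)) {
    probes <- probes[probes$kind == "pm", , drop = FALSE]
  }
  if (nrow(probes) == 0) abort_config("no probes to select from")
  arrays <- probe_arrays(probes)
  mat <- intensity_matrix(probes)
  sets <- split(
    seq_len(nrow(probes)),
    factor(probes$probeset_id, levels = unique(probes$probeset_id))
  )
  n_sets <- length(sets)
  selected_spot <- character(n_sets)
  n_probes <- integer(n_sets)
  sel_rank_sum <- numeric(n_sets)
  stat <- numeric(n_sets)
  fr_q <- numeric(n_sets)
  fr_p <- numeric(n_sets)
  expr_mat <- matrix(0, n_sets, length(arrays))
  for (i in seq_len(n_sets)) {
    idx <- sets[[i]]
    m <- mat[idx, , drop = FALSE]
    ranks <- rank_within_probeset(m)
    rs <- rank_sums(ranks)
    ids <- probes$spot_id[idx]
    sel <- select_probe(rs, rowMeans(m), ids)
    sel_i <- match(sel, ids)
    fr <- friedman_ranks_test(ranks)
    selected_spot[i] <- sel
    n_probes[i] <- length(idx)
    sel_rank_sum[i] <- rs[sel_i]
    stat[i] <- max_rank_stat(rs, length(idx))
    fr_q[i] <- fr$Q
    fr_p[i] <- fr$p
    expr_mat[i, ] <- m[sel_i, ]
  }
  selection <- tibble::tibble(
    probeset_id = names(sets),
    selected_spot = selected_spot,
    n_probes = n_probes,
    rank_sum = sel_rank_sum,
    max_rank_stat = stat,
    friedman_Q = fr_q,
    friedman_p = fr_p
  )
  expression <- tibble::tibble(probeset_id = selection$probeset_id)
  expression[arrays] <- as.data.frame(expr_mat)
  attr(expression, "stage") <- "raw"
  structure(
    list(selection = selection, expression = expression, arrays = arrays),
    class = "maxrs_fit"
  )
}

#' @export
print.maxrs_fit <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    "MAXRS selection: %d probe sets on %d arrays\n", g$n_probesets,
    length(x$arrays)
  ))
  cat(sprintf(
    "  median max-rank statistic %.2f (max attainable %d); Friedman p < 0.05 for %.1f%% of %d testable sets\n",
    g$median_max_rank_stat, length(x$arrays),
    100 * g$frac_friedman_lt_05, g$n_friedman_testable
  ))
  invisible(x)
}

#' @describeIn run_maxrs Per-probe-set selection table.
#' @param x,object A `maxrs_fit`.
#' @param ... Unused.
#' @export
tidy.maxrs_fit <- function(x, ...) x$selection

#' @describeIn run_maxrs One-row summary: probe-set counts, the median and
#'   mean of the maximum-rank-sum statistic, and the fraction of testable
#'   probe sets whose Friedman p-value falls below 0.05 (the rank-consistency
#'   fraction).
#' @export
glance.maxrs_fit <- function(x, ...) {
  selection_diagnostics(x$selection)
}

#' Summarise selection diagnostics
#'
#' Works from a selection table (e.g. re-read from `selection.tsv`), so the
#' diagnostics can be produced without re-running selection.
#'
#' @param selection Selection tibble as produced by [run_maxrs()].
#' @param p_cutoff Friedman p-value cutoff for the consistency fraction.
#' @return One-row tibble: `n_probesets`, `n_friedman_testable`,
#'   `frac_friedman_lt_05`, `mean_max_rank_stat`, `median_max_rank_stat`.
#' @export
selection_diagnostics <- function(selection, p_cutoff = 0.05) {
  testable <- !is.na(selection$friedman_p)
  tibble::tibble(
    n_probesets = nrow(selection),
    n_friedman_testable = sum(testable),
    frac_friedman_lt_05 = if (any(testable)) {
      mean(selection$friedman_p[testable] < p_cutoff)
    } else {
      NA_real_
    },
    mean_max_rank_stat = mean(selection$max_rank_stat),
    median_max_rank_stat = stats::median(selection$max_rank_stat)
  )
}
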