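#' Fit the empirical-Bayes variance prior
#'
#' Fits a scaled inverse-chi-square prior (d0 degrees of freedom, scale s0^2)
#' to the gene-wise residual variances by moment matching on the log scale.
#' With `e_g = log(s_g^2) - digamma(d_g/2) + log(d_g/2)`:
#' the prior degrees of freedom solve
#' `trigamma(d0/2) = var(e) - trigamma(d_g/2)` (monotone root found by
#' `uniroot` on d0 in `[1e-2, 1e3]`, tolerance 1e-8); a nonpositive or
#' vanishing right-hand side means the variances are no more dispersed than
#' sampling alone explains, and d0 is infinite. The prior scale is
#' `s0^2 = exp(mean(e) + digamma(d0/2) - log(d0/2))` (limit `exp(mean(e))`
#' when d0 is infinite).
#'
#' @param s2 Gene-wise residual variances (>= 10 positive values required).
#' @param df_residual Common residual degrees of freedom d_g (>= 1).
#' @return List with `d0` (possibly `Inf`) and `s02`.
#' @export
fit_variance_prior <- function(s2, df_residual) {
  if (!is.numeric(df_residual) || df_residual < 1) {
    abort_config("residual degrees of freedom must be >= 1")
  }
  if (all(s2 <= 0)) {
    abort(
      "all residual variances are zero; variance prior is degenerate",
      class = "maxrs_degenerate_error"
    )
  }
  pos <- is.finite(s2) & s2 > 0
  if (sum(pos) < 10) {
    abort(
      "need at least 10 genes with positive residual variance to fit the prior",
      class = "maxrs_insufficient_data_error"
    )
  }
  e <- log(s2[pos]) - digamma(df_residual / 2) + log(df_residual / 2)
  ebar <- mean(e)
  target <- var(e) - trigamma(df_residual / 2)
  lower <- 1e-2
  upper <- 1e3
  if (!is.finite(target) || target <= trigamma(upper / 2)) {
    # observed spread <= sampling spread even at d0 = 1000: infinite prior df
    return(list(d0 = Inf, s02 = exp(ebar)))
  }
  if (target >= trigamma(lower / 2)) {
    d0 <- lower
  } else {
    d0 <- stats::uniroot(
      function(d) trigamma(d / 2) - target,
      interval = c(lower, upper), tol = 1e-8
    )$root
  }
  list(d0 = d0, s02 = exp(ebar + digamma(d0 / 2) - log(d0 / 2)))
}

#' Moderated two-sample t-test per probe set
#'
#' Empirical-Bayes moderated t-statistics for a two-condition design. Per
#' probe set g the pooled residual variance s_g^2 (d_g = n1 + n2 - 2 df) is
#' shrunk towards the prior:
#' `s~_g^2 = (d0 s0^2 + d_g s_g^2) / (d0 + d_g)`, and
#' `t_g = logFC_g / (s~_g * sqrt(1/n1 + 1/n2))` is referred to the t
#' distribution with `d0 + d_g` degrees of freedom (normal tail when d0 is
#' infinite; the ordinary pooled-variance t when d0 = 0). Two-sided p-values
#' are adjusted by Benjamini-Hochberg and calls made at `padj <= alpha`
#' (inclusive), with a default false-discovery rate of 10%.
#'
#' The log fold change is `mean(condition2) - mean(condition1)` where the
#' conditions are ordered by first appearance in `groups` — the second-listed
#' condition is the numerator.
#'
#' @param x A log2-scale expression tibble (or `maxrs_fit`; see
#'   [log2_transform()]).
#' @param groups Group assignment tibble (`array_id`, `condition`), two
#'   conditions with >= 2 arrays each.
#' @param prior Optional list `(d0, s02)`; fitted from the data via
#'   [fit_variance_prior()] when `NULL`.
#' @param alpha FDR level for calls, default 0.10.
#' @return A tibble of class `maxrs_de` with columns `probeset_id`,
#'   `mean_group1`, `mean_group2`, `logfc`, `s2`, `df_residual`, `t`,
#'   `df_total`, `p_value`, `p_adj`, `de_call`, and attributes `d0`, `s02`,
#'   `group_levels` (c(denominator, numerator)), `n_per_group`, `alpha`.
#' @export
moderated_t_test <- function(x, groups, prior = NULL, alpha = 0.10) {
  expr <- as_expression_tbl(x)
  arrays <- probe_arrays(expr)
  validate_groups(groups, arrays = arrays)
  lev <- unique(groups$condition)
  g1 <- groups$array_id[groups$condition == lev[1]]
  g2 <- groups$array_id[groups$condition == lev[2]]
  n1 <- length(g1)
  n2 <- length(g2)
  if (n1 < 2 || n2 < 2) abort_config("each condition needs at least two arrays")
  m <- intensity_matrix(expr)
  colnames(m) <- arrays
  m1 <- m[, g1, drop = FALSE]
  m2 <- m[, g2, drop = FALSE]
  mean1 <- rowMeans(m1)
  mean2 <- rowMeans(m2)
  dg <- n1 + n2 - 2
  s2 <- (rowSums((m1 - mean1)^2) + rowSums((m2 - mean2)^2)) / dg
  if (is.null(prior)) prior <- fit_variance_prior(s2, dg)
  d0 <- prior$d0
  s02 <- prior$s02
  s2_post <- if (is.infinite(d0)) rep(s02, length(s2)) else {
    (d0 * s02 + dg * s2) / (d0 + dg)
  }
  logfc <- mean2 - mean1
  se <- sqrt(s2_post * (1 / n1 + 1 / n2))
  t_stat <- ifelse(se > 0, logfc / se,
    ifelse(logfc == 0, 0, sign(logfc) * Inf)
  )
  df_total <- d0 + dg
  p <- 2 * pt(abs(t_stat), df = df_total, lower.tail = FALSE)
  de <- tibble::tibble(
    probeset_id = expr$probeset_id,
    mean_group1 = mean1,
    mean_group2 = mean2,
    logfc = logfc,
    s2 = s2,
    df_residual = dg,
    t = t_stat,
    df_total = df_total,
    p_value = p,
    p_adj = bh_adjust(p)
  )
  de <- structure(de,
    class = c("maxrs_de", class(de)),
    d0 = d0, s02 = s02, group_levels = lev,
    n_per_group = c(n1, n2), alpha = alpha
  )
  call_de(de, alpha = alpha)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' `padj_(i) = min over j >= i of min(1, p_(j) * G / j)` on the ascending
#' sort, mapped back to input order (delegated to
#' `stats::p.adjust(method = "BH")`).
#'
#' @param p Vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same order as input.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0) {
    return(numeric(0))
  }
  if (any(!is.finite(p)) || any(p < 0 | p > 1)) {
    abort_config("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}

#' Call differential expression at an FDR level
#'
#' `de_call` is `"up"` when `p_adj <= alpha` and `logfc > 0`, `"down"` when
#' `p_adj <= alpha` and `logfc < 0`, `"none"` otherwise. The threshold is
#' inclusive.
#'
#' @param de A `maxrs_de` table (or any tibble with `p_adj` and `logfc`).
#' @param alpha FDR level, default 0.10.
#' @return `de` with an updated `de_call` column and `alpha` attribute.
#' @export
call_de <- function(de, alpha = 0.10) {
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0 || alpha >= 1) {
    abort_config("alpha must lie strictly between 0 and 1")
  }
  de$de_call <- dplyr::case_when(
    de$p_adj <= alpha & de$logfc > 0 ~ "up",
    de$p_adj <= alpha & de$logfc < 0 ~ "down",
    .default = "none"
  )
  attr(de, "alpha") <- alpha
  de
}

#' @export
print.maxrs_de <- function(x, ...) {
  g <- glance(x)
  lev <- attr(x, "group_levels")
  cat(sprintf(
    "Moderated t-test: %d probe sets, %s vs %s (logFC numerator: %s)\n",
    g$n_probesets, lev[2], lev[1], lev[2]
  ))
  cat(sprintf(
    "  prior df d0 = %s, prior variance s0^2 = %.4g; at FDR %.0f%%: %d up, %d down\n",
    format(g$d0, digits = 4), g$s02, 100 * g$alpha, g$n_up, g$n_down
  ))
  NextMethod()
}

#' @describeIn moderated_t_test Plain tibble of the per-probe-set results.
#' @param ... Unused.
#' @export
tidy.maxrs_de <- function(x, ...) {
  tibble::as_tibble(unclass(x)[names(x)])
}

#' @describeIn moderated_t_test One-row summary: gene count, fitted prior
#'   (`d0`, `s02`), FDR level and up/down call counts.
#' @export
glance.maxrs_de <- function(x, ...) {
  tibble::tibble(
    n_probesets = nrow(x),
    d0 = attr(x, "d0"),
    s02 = attr(x, "s02"),
    alpha = attr(x, "alpha"),
    n_up = sum(x$de_call == "up"),
    n_down = sum(x$de_call == "down")
  )
}
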