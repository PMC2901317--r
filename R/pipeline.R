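#' Run the full heterologous-hybridization analysis pipeline
#'
#' Executes, in order: background filtering (no-probe spots define the
#' background level; probes above it in at least one array are retained),
#' MAXRS probe selection with consistency diagnostics, quantile normalization
#' of the selected-probe matrix, optional log2 transform, and the moderated
#' t-test with Benjamini-Hochberg FDR control. All stages are deterministic.
#'
#' Output files written to `out_dir` (all TSV):
#' `filter_report.tsv`, `filtered_probes.tsv`, `selection.tsv`,
#' `expression_raw.tsv`, `expression_norm.tsv`, `de_results.tsv`,
#' `run_summary.tsv`, and a parameter/count log `run.log`. On error, files
#' already written for this run are removed.
#'
#' @param probe_file Path to the probe table TSV ([read_probe_table()]).
#' @param group_file Path to the group file TSV ([read_group_file()]).
#' @param out_dir Output directory (created if needed).
#' @param bg_percentile Background percentile, default 95.
#' @param bg_pooled Pool background spots across arrays? Default per-array.
#' @param log_floor Floor for the log2 transform, default 1.
#' @param no_log Skip the log2 transform and test normalized intensities
#'   directly.
#' @param fdr FDR level for DE calls, default 0.10.
#' @param quiet Suppress the stage messages on stderr.
#' @return Invisibly, a list with the in-memory stage results: `background`,
#'   `filtered`, `fit`, `expression`, `de`, `summary`.
#' @export
run_pipeline <- function(probe_file, group_file, out_dir,
                         bg_percentile = 95, bg_pooled = FALSE,
                         log_floor = 1, no_log = FALSE, fdr = 0.10,
                         quiet = FALSE) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  written <- character(0)
  emit <- function(...) if (!quiet) message(...)
  log_lines <- character(0)
  note <- function(...) {
    line <- sprintf(...)
    log_lines <<- c(log_lines, line)
    emit(line)
  }
  put <- function(x, name) {
    path <- file.path(out_dir, name)
    write_table(x, path)
    written <<- c(written, path)
    path
  }
  stage <- "validation"
  res <- tryCatch(
    {
      probes <- read_probe_table(probe_file)
      groups <- read_group_file(group_file)
      validate_groups(groups, arrays = probe_arrays(probes))
      note("arrays: %s", paste(probe_arrays(probes), collapse = ", "))
      note(
        "design: %s", paste(sprintf("%s=%s", groups$array_id, groups$condition),
          collapse = ", "
        )
      )

      stage <- "background_filter"
      bg <- estimate_background(probes, q = bg_percentile, pooled = bg_pooled)
      flt <- apply_background_filter(probes, bg)
      r <- flt$report
      note(
        "background: %gth percentile (%s); %d/%d probes above background in >=1 array (%.1f%%); %d/%d probe sets retained",
        bg_percentile, if (bg_pooled) "pooled" else "per-array",
        r$n_probes_retained, r$n_probes_total,
        100 * r$fraction_probes_retained,
        r$n_probesets_retained, r$n_probesets_total
      )
      put(flt$report, "filter_report.tsv")
      put(flt$probes, "filtered_probes.tsv")

      stage <- "maxrs_selection"
      fit <- run_maxrs(flt)
      d <- glance(fit)
      note(
        "selection: %d probe sets; Friedman p<0.05 for %.1f%% of %d testable sets; median max-rank statistic %.2f",
        d$n_probesets, 100 * d$frac_friedman_lt_05, d$n_friedman_testable,
        d$median_max_rank_stat
      )
      put(fit$selection, "selection.tsv")
      put(fit$expression, "expression_raw.tsv")

      stage <- "normalization"
      expr <- quantile_normalize(fit)
      if (!no_log) expr <- log2_transform(expr, floor = log_floor)
      note(
        "normalization: quantile%s",
        if (no_log) ", no log transform" else {
          sprintf(", then log2 with floor %g", log_floor)
        }
      )
      put(expr, "expression_norm.tsv")

      stage <- "de_test"
      de <- moderated_t_test(expr, groups, alpha = fdr)
      g <- glance(de)
      lev <- attr(de, "group_levels")
      note(
        "moderated t: d0 = %s, s0^2 = %.4g; logFC = %s - %s; FDR %.0f%%: %d up, %d down",
        format(g$d0, digits = 4), g$s02, lev[2], lev[1], 100 * fdr,
        g$n_up, g$n_down
      )
      put(tidy(de), "de_results.tsv")

      summary_tbl <- tibble::tibble(
        bg_percentile = bg_percentile,
        bg_pooled = bg_pooled,
        log_floor = if (no_log) NA_real_ else log_floor,
        fdr = fdr,
        n_probes_total = r$n_probes_total,
        n_probes_retained = r$n_probes_retained,
        fraction_probes_retained = r$fraction_probes_retained,
        n_probesets_total = r$n_probesets_total,
        n_probesets_retained = r$n_probesets_retained,
        frac_friedman_lt_05 = d$frac_friedman_lt_05,
        median_max_rank_stat = d$median_max_rank_stat,
        d0 = g$d0,
        s02 = g$s02,
        n_up = g$n_up,
        n_down = g$n_down
      )
      put(summary_tbl, "run_summary.tsv")
      writeLines(log_lines, file.path(out_dir, "run.log"))
      list(
        background = bg, filtered = flt, fit = fit, expression = expr,
        de = de, summary = summary_tbl
      )
    },
    error = function(e) {
      unlink(written)
      abort(
        paste0("pipeline failed at stage `", stage, "`: ",
          conditionMessage(e)),
        class = "maxrs_stage_error", parent = e
      )
    }
  )
  invisible(res)
}
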