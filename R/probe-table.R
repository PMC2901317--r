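#' Read a probe-level intensity table
#'
#' The interchange format is a tab-separated file with a header row
#' `spot_id  probeset_id  kind  <array1> ... <arrayM>`. Each row is one spot:
#' a perfect-match probe (`kind = "pm"`, with its probe-set membership in
#' `probeset_id`) or a no-probe background spot (`kind = "background"`,
#' `probeset_id` written as `"."`). Intensities are nonnegative reals, one
#' column per array; column order defines the array order used by every
#' downstream stage.
#'
#' Mismatch (MM) probes are not part of the method and a file containing
#' `kind = "mm"` rows is rejected with an error rather than silently filtered,
#' so user mistakes surface early.
#'
#' @param path Path to a tab-separated probe table.
#' @return A tibble with columns `spot_id`, `probeset_id` (`NA` for background
#'   spots), `kind`, and one numeric intensity column per array.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c(
#'   "spot_id\tprobeset_id\tkind\tA1\tA2",
#'   "s1\tps1\tpm\t120.5\t80.2",
#'   "s2\tps1\tpm\t40.0\t35.1",
#'   "b1\t.\tbackground\t12.0\t15.3"
#' ), tf)
#' read_probe_table(tf)
#' @export
read_probe_table <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("probe table not found: ", path), class = "maxrs_io_error")
  }
  raw <- readr::read_tsv(path,
    col_types = readr::cols(.default = readr::col_character()),
    na = character(), progress = FALSE
  )
  if (ncol(raw) < length(PROBE_FIXED_COLS) + 2 ||
    !identical(names(raw)[seq_along(PROBE_FIXED_COLS)], PROBE_FIXED_COLS)) {
    abort_format(paste0(
      "probe table header must be `spot_id  probeset_id  kind` followed by ",
      "at least two array columns"
    ))
  }
  arrays <- setdiff(names(raw), PROBE_FIXED_COLS)
  probes <- raw
  probes$probeset_id[probes$probeset_id %in% c(".", "")] <- NA_character_
  for (a in arrays) {
    v <- suppressWarnings(as.numeric(raw[[a]]))
    bad <- is.na(v) | !is.finite(v)
    if (any(bad)) {
      abort_format(paste0(
        "non-numeric or non-finite intensity in array `", a, "` (row ",
        which(bad)[1], ")"
      ))
    }
    probes[[a]] <- v
  }
  validate_probe_table(probes)
  probes
}

#' Validate a probe table
#'
#' Checks the invariants of the probe-table contract: unique spot identifiers,
#' probe-set membership present for every PM probe and absent for every
#' background spot, only `pm`/`background` spot kinds, finite nonnegative
#' intensities, and at least one spot of each kind.
#'
#' @param probes A probe table tibble (see [read_probe_table()]).
#' @return `probes`, invisibly, if valid; otherwise an error.
#' @export
validate_probe_table <- function(probes) {
  if (!is.data.frame(probes) || !all(PROBE_FIXED_COLS %in% names(probes))) {
    abort_format("not a probe table: missing spot_id/probeset_id/kind columns")
  }
  arrays <- probe_arrays(probes)
  if (length(arrays) < 1) abort_format("probe table has no array columns")
  if (anyDuplicated(probes$spot_id)) {
    abort_format(paste0(
      "duplicate spot_id: ",
      probes$spot_id[duplicated(probes$spot_id)][1]
    ))
  }
  if (any(probes$kind %in% c("mm", "mismatch"))) {
    abort_format(paste0(
      "mismatch (MM) probes found; this method uses perfect-match probes only ",
      "- remove MM rows before import"
    ))
  }
  if (!all(probes$kind %in% c("pm", "background"))) {
    abort_format(paste0(
      "unknown spot kind: ",
      setdiff(unique(probes$kind), c("pm", "background"))[1]
    ))
  }
  pm <- probes$kind == "pm"
  if (any(pm & is.na(probes$probeset_id))) {
    abort_format("pm probe with empty probeset_id")
  }
  if (any(!pm & !is.na(probes$probeset_id))) {
    abort_format("background spot with a probeset_id (expected `.`)")
  }
  if (!any(pm)) abort_format("probe table has no pm probes")
  if (all(pm)) abort_format("probe table has no background spots")
  m <- intensity_matrix(probes)
  if (any(!is.finite(m))) abort_format("non-finite intensity value")
  if (any(m < 0)) abort_format("negative intensity value")
  invisible(probes)
}

#' Write a probe table
#'
#' Inverse of [read_probe_table()]: background spots get `probeset_id = "."`.
#' Values round-trip at full double precision.
#'
#' @param probes A probe table tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_probe_table <- function(probes, path) {
  validate_probe_table(probes)
  out <- probes
  out$probeset_id[is.na(out$probeset_id)] <- "."
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read an array-to-condition group file
#'
#' Tab-separated with header `array_id  condition`. The design must have
#' exactly two conditions with at least two arrays each. The condition listed
#' second (by first appearance) is the numerator of downstream log fold
#' changes.
#'
#' @param path Path to the group file.
#' @return A tibble with columns `array_id`, `condition`.
#' @export
read_group_file <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("group file not found: ", path), class = "maxrs_io_error")
  }
  groups <- readr::read_tsv(path,
    col_types = readr::cols(.default = readr::col_character()),
    na = character(), progress = FALSE
  )
  if (!identical(names(groups), c("array_id", "condition"))) {
    abort_format("group file header must be `array_id  condition`")
  }
  validate_groups(groups)
  groups
}

#' Validate a group assignment
#'
#' @param groups Tibble with `array_id`, `condition`.
#' @param arrays Optional character vector of array ids that must be assigned
#'   exactly once (e.g. the arrays of a probe table).
#' @return `groups`, invisibly.
#' @export
validate_groups <- function(groups, arrays = NULL) {
  if (!is.data.frame(groups) ||
    !all(c("array_id", "condition") %in% names(groups))) {
    abort_format("groups must have columns `array_id` and `condition`")
  }
  if (anyDuplicated(groups$array_id)) {
    abort_format("an array is assigned to more than one condition")
  }
  lev <- unique(groups$condition)
  if (length(lev) != 2) {
    abort_format(paste0(
      "exactly two conditions required, found ", length(lev)
    ))
  }
  n <- table(factor(groups$condition, levels = lev))
  if (any(n < 2)) {
    abort_format("each condition needs at least two arrays")
  }
  if (!is.null(arrays)) {
    missing_arr <- setdiff(arrays, groups$array_id)
    extra_arr <- setdiff(groups$array_id, arrays)
    if (length(missing_arr) || length(extra_arr)) {
      abort_consistency(paste0(
        "group file and probe table disagree on arrays",
        if (length(missing_arr)) paste0("; unassigned: ", paste(missing_arr, collapse = ", ")),
        if (length(extra_arr)) paste0("; unknown: ", paste(extra_arr, collapse = ", "))
      ))
    }
  }
  invisible(groups)
}

#' Write a result table as TSV
#'
#' Deterministic column and row order (as stored); doubles are written with
#' full round-trip precision so re-reading reproduces the values exactly.
#'
#' @param x A data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_table <- function(x, path) {
  readr::write_tsv(x, path, progress = FALSE)
  invisible(path)
}
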