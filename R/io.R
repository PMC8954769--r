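# CSV dialects -----------------------------------------------------------
#
# profiles:   subject,route,dose_mg_per_kg,time_h,conc_ng_per_ml,blq_flag
# assay data: level_ng_per_ml,replicate,set,area  (or area_ratio / is_area)
# stability:  condition,level_ng_per_ml,replicate,conc_ng_per_ml
# decay:      matrix,replicate,time_min,pct_remaining
#
# Numeric columns round-trip losslessly: writing uses full double precision.

read_table_checked <- function(path, required, what, optional = character()) {
  if (!file.exists(path)) abort(sprintf("Input file not found: %s", path))
  tab <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  assert_columns(tab, required, sprintf("%s (%s)", what, path))
  unknown <- setdiff(names(tab), c(required, optional))
  if (length(unknown) > 0L) {
    warn(sprintf("%s: ignoring unknown column(s): %s",
                 what, paste(unknown, collapse = ", ")))
  }
  tab
}

#' Read a concentration-time profile table
#'
#' Reads the `subject,route,dose_mg_per_kg,time_h,conc_ng_per_ml[,blq_flag]`
#' CSV dialect. Rows are sorted by time within subject; a warning is issued
#' if the file was unsorted.
#'
#' @param path CSV file path.
#' @return A profile tibble suitable for [nca()].
#' @export
read_profile_table <- function(path) {
  tab <- read_table_checked(
    path,
    required = c("subject", "route", "dose_mg_per_kg", "time_h", "conc_ng_per_ml"),
    optional = "blq_flag",
    what = "profile table"
  )
  sorted <- tab |>
    dplyr::arrange(.data$subject, .data$route, .data$time_h)
  if (!identical(sorted$time_h, tab$time_h) ||
      !identical(sorted$subject, tab$subject)) {
    warn(sprintf("Profile table %s was not sorted by time; sorted on read.", path))
  }
  sorted
}

#' Read an assay peak-area table
#'
#' Reads the `level_ng_per_ml,replicate,set,area` dialect. Both response
#' dialects are accepted: a precomputed `area_ratio` column, or `area`
#' (optionally with a companion `is_area` column for the internal standard).
#'
#' @param path CSV file path.
#' @return A tibble.
#' @export
read_assay_table <- function(path) {
  tab <- read_table_checked(
    path,
    required = c("level_ng_per_ml", "replicate", "set"),
    optional = c("area", "area_ratio", "is_area", "analyte"),
    what = "assay table"
  )
  if (!any(c("area", "area_ratio") %in% names(tab))) {
    abort(sprintf("Assay table %s needs an `area` or `area_ratio` column.", path))
  }
  tab
}

#' Read a stability table
#'
#' Reads the `condition,level_ng_per_ml,replicate,conc_ng_per_ml` dialect.
#'
#' @param path CSV file path.
#' @return A tibble suitable for [stability_summary()].
#' @export
read_stability_table <- function(path) {
  read_table_checked(
    path,
    required = c("condition", "level_ng_per_ml", "replicate", "conc_ng_per_ml"),
    what = "stability table"
  )
}

#' Read a decay time-course table
#'
#' Reads the `matrix,replicate,time_min,pct_remaining` dialect.
#'
#' @param path CSV file path.
#' @return A tibble suitable for [kinetics_summary()].
#' @export
read_decay_table <- function(path) {
  read_table_checked(
    path,
    required = c("matrix", "replicate", "time_min", "pct_remaining"),
    what = "decay table"
  )
}

#' Write a report table
#'
#' Writes a tibble as CSV at full numeric precision (computation and
#' presentation rounding are kept separate; use `digits` to apply
#' significant-figure presentation rounding to numeric columns).
#'
#' @param data A data frame.
#' @param path Output CSV path.
#' @param digits Optional significant figures for presentation rounding;
#'   `NULL` (default) writes full precision.
#' @return `data`, invisibly.
#' @export
write_report <- function(data, path, digits = NULL) {
  out <- data
  if (!is.null(digits)) {
    out <- dplyr::mutate(out, dplyr::across(dplyr::where(is.numeric),
                                            ~ signif(.x, digits)))
  }
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(out, path, progress = FALSE)
  invisible(data)
}
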