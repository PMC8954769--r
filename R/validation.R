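#' Accuracy as percent relative error
#'
#' Relative error of the mean measured concentration against nominal,
#' `100 * |mean(measured) - nominal| / nominal`. Reported as an absolute
#' percentage by convention; set `signed = TRUE` to keep the sign.
#'
#' @param measured Numeric vector of measured concentrations (ng/mL).
#' @param nominal Nominal concentration (ng/mL), > 0.
#' @param signed If `TRUE`, return the signed relative error.
#'
#' @return A single percentage.
#' @export
#' @examples
#' accuracy_re(c(4.9, 4.9, 4.9), 5)  # 2
accuracy_re <- function(measured, nominal, signed = FALSE) {
  assert_number(nominal, "nominal", lower = 0, strict_lower = TRUE)
  if (length(measured) < 1L) abort("`measured` must be non-empty.")
  re <- 100 * (mean(measured) - nominal) / nominal
  if (signed) re else abs(re)
}

#' Precision as percent coefficient of variation
#'
#' `100 * sd(measured) / mean(measured)` using the sample (n - 1) SD.
#'
#' @param measured Numeric vector, length >= 2, non-zero mean.
#' @return A single percentage.
#' @export
#' @examples
#' precision_cv(c(95, 100, 105))
precision_cv <- function(measured) {
  if (length(measured) < 2L) abort("`measured` needs >= 2 replicates for a CV.")
  m <- mean(measured)
  if (m == 0) abort("Mean of `measured` is zero; CV undefined.")
  100 * sd(measured) / m
}

#' QC accuracy/precision acceptance
#'
#' Pass if and only if both the relative error and the CV are within the
#' guideline limit: 20% at the LLOQ and 15% at all other levels (inclusive
#' boundaries).
#'
#' @param re_pct Absolute percent relative error.
#' @param cv_pct Percent CV.
#' @param is_lloq Is this the LLOQ level?
#' @return Logical.
#' @export
qc_acceptance <- function(re_pct, cv_pct, is_lloq = FALSE) {
  threshold <- ifelse(is_lloq, 20, 15)
  abs(re_pct) <= threshold & cv_pct <= threshold
}

#' Accuracy and precision summary table
#'
#' Summarizes replicate measured concentrations per nominal level into the
#' standard validation layout: mean +/- SD, absolute and signed %RE, CV%, and
#' the guideline pass flag.
#'
#' @param data A data frame with columns `level_ng_per_ml` (nominal) and
#'   `conc_ng_per_ml` (measured).
#' @param scope Label stored in the output (`"intraday"` or `"interday"`).
#' @param lloq The LLOQ level (default: smallest nominal present).
#'
#' @return A tibble with one row per nominal level.
#' @export
qc_summary <- function(data, scope = c("intraday", "interday"), lloq = NULL) {
  scope <- match.arg(scope)
  assert_columns(data, c("level_ng_per_ml", "conc_ng_per_ml"), "QC table")
  lloq <- lloq %||% min(data$level_ng_per_ml)
  data |>
    dplyr::group_by(nominal = .data$level_ng_per_ml) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_measured = mean(.data$conc_ng_per_ml),
      sd_measured = sd(.data$conc_ng_per_ml),
      re_pct = accuracy_re(.data$conc_ng_per_ml, .data$nominal[1]),
      re_signed_pct = accuracy_re(.data$conc_ng_per_ml, .data$nominal[1], signed = TRUE),
      cv_pct = precision_cv(.data$conc_ng_per_ml),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      scope = scope,
      is_lloq = .data$nominal == lloq,
      pass = qc_acceptance(.data$re_pct, .data$cv_pct, .data$is_lloq)
    )
}

# mean/sd/cv of one Matuszewski ratio; per-replicate numerators are divided
# by the mean of the denominator set, so the ratio of means is recovered and
# the spread reflects the numerator set only.
ratio_stats <- function(num, den) {
  if (length(num) < 1L || length(den) < 1L) abort("Both sets must be non-empty.")
  md <- mean(den)
  if (md == 0) abort("Denominator set mean is zero.")
  r <- 100 * num / md
  list(pct = mean(r), sd = if (length(r) >= 2) sd(r) else NA_real_,
       cv = if (length(r) >= 2) 100 * sd(r) / mean(r) else NA_real_)
}

matuszewski_metric <- function(sets, num_set, den_set, prefix) {
  assert_columns(sets, c("analyte", "level_ng_per_ml", "set", "area"),
                 "Matuszewski table")
  sets |>
    dplyr::group_by(.data$analyte, .data$level_ng_per_ml) |>
    dplyr::group_modify(function(d, key) {
      st <- ratio_stats(d$area[d$set == num_set], d$area[d$set == den_set])
      tibble("{prefix}_pct" := st$pct, "{prefix}_sd" := st$sd,
             "{prefix}_cv_pct" := st$cv)
    }) |>
    dplyr::ungroup()
}

#' Matrix effect (Matuszewski set 2 / set 1)
#'
#' Percent matrix effect per analyte and level:
#' `100 * mean(set2) / mean(set1)`, where set 1 is the neat solution and
#' set 2 the post-extraction spike. Values below 100% indicate ionization
#' suppression. The SD and CV are computed over per-replicate set-2 areas
#' divided by the set-1 mean.
#'
#' @param sets A Matuszewski table with columns `analyte`, `level_ng_per_ml`,
#'   `set` (`"set1"`/`"set2"`/`"set3"`), `replicate`, `area`
#'   (see [simulate_matuszewski()]).
#' @return A tibble with `me_pct`, `me_sd`, `me_cv_pct` per analyte and level.
#' @export
matrix_effect <- function(sets) matuszewski_metric(sets, "set2", "set1", "me")

#' Extraction recovery (Matuszewski set 3 / set 2)
#'
#' `100 * mean(set3) / mean(set2)`: the true extraction recovery, insulated
#' from the matrix effect because both sets carry the same matrix.
#'
#' @inheritParams matrix_effect
#' @return A tibble with `recovery_pct`, `recovery_sd`, `recovery_cv_pct`.
#' @export
recovery <- function(sets) matuszewski_metric(sets, "set3", "set2", "recovery")

#' Process efficiency (Matuszewski set 3 / set 1)
#'
#' `100 * mean(set3) / mean(set1)`: the overall efficiency of extraction and
#' ionization combined. Computed from the same set means as [matrix_effect()]
#' and [recovery()], so `pe = me * recovery / 100` holds exactly.
#'
#' @inheritParams matrix_effect
#' @return A tibble with `pe_pct`, `pe_sd`, `pe_cv_pct`.
#' @export
process_efficiency <- function(sets) matuszewski_metric(sets, "set3", "set1", "pe")

#' Internal-standard normalization of a matrix-effect metric
#'
#' `100 * analyte_metric / is_metric`: expresses an analyte matrix-effect,
#' recovery, or process-efficiency percentage relative to the internal
#' standard's, cancelling shared suppression.
#'
#' @param analyte_metric_pct Analyte metric (percent).
#' @param is_metric_pct Internal-standard metric (percent), > 0.
#' @return Percentage(s).
#' @export
#' @examples
#' is_normalize(80.76, 77.61)  # ~104.06
is_normalize <- function(analyte_metric_pct, is_metric_pct) {
  if (any(is_metric_pct <= 0)) abort("`is_metric_pct` must be > 0.")
  100 * analyte_metric_pct / is_metric_pct
}

#' Full Matuszewski summary with IS normalization
#'
#' Joins matrix effect, recovery, and process efficiency per analyte and
#' level, and adds the IS-normalized columns (analyte metric divided by the
#' internal-standard metric at the same set means).
#'
#' @inheritParams matrix_effect
#' @return A tibble with one row per analyte/level carrying all three metrics
#'   and, for analyte rows, `me_is_norm_pct`, `recovery_is_norm_pct`,
#'   `pe_is_norm_pct`.
#' @export
matuszewski_summary <- function(sets) {
  out <- matrix_effect(sets) |>
    dplyr::left_join(recovery(sets), by = c("analyte", "level_ng_per_ml")) |>
    dplyr::left_join(process_efficiency(sets), by = c("analyte", "level_ng_per_ml"))
  is_row <- out[out$analyte == "is", ]
  if (nrow(is_row) == 1L) {
    out <- out |>
      dplyr::mutate(
        me_is_norm_pct = ifelse(.data$analyte == "analyte",
                                is_normalize(.data$me_pct, is_row$me_pct), NA_real_),
        recovery_is_norm_pct = ifelse(.data$analyte == "analyte",
                                      is_normalize(.data$recovery_pct, is_row$recovery_pct), NA_real_),
        pe_is_norm_pct = ifelse(.data$analyte == "analyte",
                                is_normalize(.data$pe_pct, is_row$pe_pct), NA_real_)
      )
  }
  out
}

#' Stability percentage
#'
#' `100 * mean(measured) / reference`, with the SD taken over the
#' per-replicate percentage ratios. By convention the reference is the
#' nominal concentration; pass freshly prepared sample means via `reference`
#' for the fresh-reference mode.
#'
#' @param measured Measured concentrations (ng/mL), non-empty.
#' @param reference Reference concentration (ng/mL), > 0.
#' @return A one-row tibble with `stability_pct`, `sd_pct`, `n`.
#' @export
stability_pct <- function(measured, reference) {
  assert_number(reference, "reference", lower = 0, strict_lower = TRUE)
  if (length(measured) < 1L) abort("`measured` must be non-empty.")
  r <- 100 * measured / reference
  tibble(
    stability_pct = mean(r),
    sd_pct = if (length(r) >= 2) sd(r) else NA_real_,
    n = length(r)
  )
}

#' Stability summary table
#'
#' One row per storage condition and nominal level, in the standard
#' stability-table layout.
#'
#' @param data A data frame with columns `condition`, `level_ng_per_ml`,
#'   `replicate`, `conc_ng_per_ml`.
#' @param reference `"nominal"` (default) to reference each level's nominal
#'   concentration, or a data frame with `condition` (optional),
#'   `level_ng_per_ml`, and `reference_ng_per_ml` columns.
#' @return A tibble with `condition`, `level_ng_per_ml`, `stability_pct`,
#'   `sd_pct`, `n`.
#' @export
stability_summary <- function(data, reference = "nominal") {
  assert_columns(data, c("condition", "level_ng_per_ml", "conc_ng_per_ml"),
                 "stability table")
  ref_for <- function(condition, level) {
    if (identical(reference, "nominal")) return(level)
    assert_columns(reference, c("level_ng_per_ml", "reference_ng_per_ml"),
                   "reference table")
    hit <- reference[reference$level_ng_per_ml == level, ]
    if ("condition" %in% names(hit) && any(hit$condition == condition)) {
      hit <- hit[hit$condition == condition, ]
    }
    if (nrow(hit) < 1L) abort(sprintf("No reference for level %g.", level))
    hit$reference_ng_per_ml[1]
  }
  data |>
    dplyr::group_by(.data$condition, .data$level_ng_per_ml) |>
    dplyr::group_modify(function(d, key) {
      stability_pct(d$conc_ng_per_ml,
                    ref_for(key$condition, key$level_ng_per_ml))
    }) |>
    dplyr::ungroup()
}

#' Chromatographic signal-to-noise ratio
#'
#' `(apex intensity - baseline mean) / baseline SD`, with the baseline
#' statistics taken over the trace's peak-free baseline window and the apex
#' intensity read at the grid point nearest the peak apex. Eligibility for
#' the LLOQ requires S/N strictly greater than 10.
#'
#' @param trace A `chromatogram` (see [simulate_chromatogram()]).
#' @return A one-row tibble with `s_n`, `apex_intensity`, `baseline_mean`,
#'   `baseline_sd`, `lloq_eligible`. A zero-variance baseline with signal
#'   above it yields `Inf` with a warning; a flat trace yields 0.
#' @export
signal_to_noise <- function(trace) {
  stopifnot(inherits(trace, "chromatogram"))
  t <- trace$trace$time_min
  y <- trace$trace$intensity
  in_window <- t >= trace$baseline_window[1] & t <= trace$baseline_window[2]
  if (!any(in_window)) abort("Baseline window contains no grid points.")
  base <- y[in_window]
  base_mean <- mean(base)
  base_sd <- if (length(base) >= 2) sd(base) else 0
  apex <- y[which.min(abs(t - trace$peak_apex_time))]
  signal <- apex - base_mean
  s_n <- if (base_sd == 0) {
    if (abs(signal) < .Machine$double.eps^0.5) {
      0
    } else {
      warn("Zero-variance baseline: signal-to-noise reported as infinite.")
      Inf
    }
  } else {
    signal / base_sd
  }
  tibble(
    s_n = s_n,
    apex_intensity = apex,
    baseline_mean = base_mean,
    baseline_sd = base_sd,
    lloq_eligible = s_n > 10
  )
}
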