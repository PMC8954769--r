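#' Fit a first-order elimination constant from a decay time course
#'
#' Ordinary least-squares regression of the natural log of percent remaining
#' on incubation time; the elimination rate constant is the negated slope and
#' the half-life is `ln(2)/ke`. Natural logarithms are used throughout so the
#' slope is the rate constant directly. Replicates are pooled into a single
#' regression by default; use [fit_ke_each()] for per-replicate fits.
#'
#' A non-decaying series (slope >= 0) is returned with `decaying = FALSE`,
#' `ke <= 0`, and `t_half = NA` (undefined sentinel) rather than an error:
#' stable incubations are an expected outcome.
#'
#' @param timecourse A data frame with columns `time_min` and `pct_remaining`
#'   (optionally `replicate`, `matrix`), e.g. from [simulate_decay()].
#'
#' @return An object of class `kinetics_fit` with `ke` (1/min), `t_half`
#'   (min), `r2`, `n_points`, `decaying`, `matrix`.
#' @seealso [half_life()], [predict_remaining()], [kinetics_summary()]
#' @export
#' @examples
#' fit_ke(simulate_decay(t_half = 44, residual_cv = 0))
fit_ke <- function(timecourse) {
  assert_columns(timecourse, c("time_min", "pct_remaining"), "decay table")
  t <- timecourse$time_min
  p <- timecourse$pct_remaining
  if (any(!is.finite(t)) || any(t < 0)) abort("Times must be finite and non-negative.")
  if (any(p <= 0)) abort("All `pct_remaining` values must be > 0 (log undefined otherwise).")
  if (length(unique(t)) < 2L) {
    abort("At least two distinct time points are required (rank-deficient otherwise).")
  }
  fit <- lm(log(p) ~ t)
  slope <- unname(coef(fit)[2])
  constant <- sd(log(p)) == 0
  if (constant) slope <- 0  # flat series: exact zero, not floating-point dust
  # r2 from the correlation directly; summary.lm warns on exact fits
  r2 <- if (constant) NA_real_ else cor(t, log(p))^2
  ke <- -slope
  structure(
    list(
      ke = ke,
      t_half = half_life(ke),
      r2 = r2,
      n_points = length(t),
      decaying = ke > 0,
      matrix = if ("matrix" %in% names(timecourse))
        as.character(timecourse$matrix[1]) else NA_character_
    ),
    class = "kinetics_fit"
  )
}

#' Per-replicate elimination fits
#'
#' Runs [fit_ke()] separately within each replicate and returns one tidy row
#' per fit, for when replicate-level half-lives (mean +/- SD) are wanted
#' instead of the pooled regression.
#'
#' @inheritParams fit_ke
#' @return A tibble with `replicate`, `ke_per_min`, `t_half_min`, `r2`, `n`.
#' @export
fit_ke_each <- function(timecourse) {
  assert_columns(timecourse, c("time_min", "pct_remaining"), "decay table")
  if (!"replicate" %in% names(timecourse)) timecourse$replicate <- 1L
  timecourse |>
    dplyr::group_by(.data$replicate) |>
    dplyr::group_modify(function(d, key) glance(fit_ke(d))[, c("ke_per_min", "t_half_min", "r2", "n")]) |>
    dplyr::ungroup()
}

#' Kinetics summary across incubation matrices
#'
#' Pooled log-linear fit per matrix label, in the standard output layout.
#'
#' @param data A decay table with columns `matrix`, `time_min`,
#'   `pct_remaining` (and optionally `replicate`).
#' @return A tibble with `matrix`, `ke_per_min`, `t_half_min`, `r2`, `n`.
#' @export
kinetics_summary <- function(data) {
  assert_columns(data, c("matrix", "time_min", "pct_remaining"), "decay table")
  data |>
    dplyr::group_by(.data$matrix) |>
    dplyr::group_modify(function(d, key) glance(fit_ke(d))[, c("ke_per_min", "t_half_min", "r2", "n")]) |>
    dplyr::ungroup()
}

#' Half-life from a first-order rate constant
#'
#' `t_half = ln(2) / ke`. Non-positive rate constants have no half-life and
#' return `NA` (undefined sentinel).
#'
#' @param ke Rate constant(s), 1/min (or any reciprocal time unit; the result
#'   is in the matching time unit).
#' @return Half-life/lives in the matching time unit.
#' @export
#' @examples
#' half_life(log(2) / 60)  # 60
half_life <- function(ke) {
  ifelse(is.finite(ke) & ke > 0, log(2) / ke, NA_real_)
}

#' Percent remaining under first-order decay
#'
#' `100 * exp(-ke * t)`.
#'
#' @param ke Rate constant (1/min).
#' @param t Time(s) (min), >= 0.
#' @return Percent remaining.
#' @export
predict_remaining <- function(ke, t) {
  if (any(!is.finite(ke))) abort("`ke` must be finite.")
  if (any(t < 0)) abort("`t` must be non-negative.")
  100 * exp(-ke * t)
}

#' @export
print.kinetics_fit <- function(x, ...) {
  cat("<kinetics_fit>\n")
  if (!is.na(x$matrix)) cat(sprintf("  matrix: %s\n", x$matrix))
  if (x$decaying) {
    cat(sprintf("  ke = %s /min, t1/2 = %s min (r2 = %.4f, n = %d)\n",
                format_sigfig(x$ke), format_sigfig(x$t_half), x$r2, x$n_points))
  } else {
    cat(sprintf("  non-decaying series: ke = %s /min, half-life undefined (n = %d)\n",
                format_sigfig(x$ke), x$n_points))
  }
  invisible(x)
}

#' @rdname fit_ke
#' @param x A `kinetics_fit`.
#' @param ... Unused.
#' @export
tidy.kinetics_fit <- function(x, ...) {
  tibble(
    term = c("ke_per_min", "t_half_min"),
    estimate = c(x$ke, x$t_half)
  )
}

#' @rdname fit_ke
#' @export
glance.kinetics_fit <- function(x, ...) {
  tibble(
    ke_per_min = x$ke, t_half_min = x$t_half, r2 = x$r2,
    n = x$n_points, decaying = x$decaying, matrix = x$matrix
  )
}
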