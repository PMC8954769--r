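#' Plot a calibration fit
#'
#' Standards and the fitted weighted line on log-log axes, the conventional
#' way a 2--3000 ng/mL calibration is inspected.
#'
#' @param object A `calibration_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.calibration_fit <- function(object, ...) {
  d <- object$data
  line <- tibble(
    level_ng_per_ml = exp(seq(log(min(d$level_ng_per_ml)),
                              log(max(d$level_ng_per_ml)), length.out = 100))
  )
  line$area_ratio <- object$intercept + object$slope * line$level_ng_per_ml
  ggplot2::ggplot(d, ggplot2::aes(.data$level_ng_per_ml, .data$area_ratio)) +
    ggplot2::geom_line(data = line, colour = "steelblue") +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(
      x = "Nominal concentration (ng/mL)",
      y = "Analyte:IS peak-area ratio",
      title = sprintf("Weighted calibration (%s), r = %.4f",
                      object$weighting, object$r)
    )
}

#' Plot a decay time course with its log-linear fit
#'
#' @param data A decay table (`time_min`, `pct_remaining`).
#' @param fit Optional `kinetics_fit`; defaults to the pooled fit of `data`.
#' @return A ggplot with percent remaining on a log scale.
#' @export
plot_decay <- function(data, fit = fit_ke(data)) {
  grid <- tibble(time_min = seq(min(data$time_min), max(data$time_min),
                                length.out = 100))
  grid$pct_remaining <- 100 * exp(-fit$ke * grid$time_min) *
    exp(mean(log(data$pct_remaining) + fit$ke * data$time_min) - log(100))
  ggplot2::ggplot(data, ggplot2::aes(.data$time_min, .data$pct_remaining)) +
    ggplot2::geom_line(data = grid, colour = "steelblue") +
    ggplot2::geom_point() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(
      x = "Time (min)", y = "Remaining (%)",
      title = if (fit$decaying)
        sprintf("First-order decay: t1/2 = %s min", format_sigfig(fit$t_half))
      else "Non-decaying series"
    )
}

#' Plot concentration-time profiles
#'
#' Semilogarithmic spaghetti plot of per-subject profiles, split by route.
#' BLQ observations (if flagged) are shown as open symbols.
#'
#' @param profiles A profile tibble (`subject`, `route`, `time_h`,
#'   `conc_ng_per_ml`, optionally `blq_flag`).
#' @return A ggplot.
#' @export
plot_profiles <- function(profiles) {
  assert_columns(profiles, c("subject", "route", "time_h", "conc_ng_per_ml"),
                 "profile table")
  if (!"blq_flag" %in% names(profiles)) profiles$blq_flag <- FALSE
  ggplot2::ggplot(
    dplyr::filter(profiles, .data$conc_ng_per_ml > 0),
    ggplot2::aes(.data$time_h, .data$conc_ng_per_ml,
                 group = .data$subject, colour = factor(.data$subject))
  ) +
    ggplot2::geom_line(alpha = 0.6) +
    ggplot2::geom_point(ggplot2::aes(shape = .data$blq_flag)) +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 16, `TRUE` = 1),
                                name = "BLQ") +
    ggplot2::scale_y_log10() +
    ggplot2::facet_wrap(~route, scales = "free_y") +
    ggplot2::labs(x = "Time (h)", y = "Concentration (ng/mL)",
                  colour = "Subject")
}

#' Plot a chromatographic trace
#'
#' @param object A `chromatogram`.
#' @param ... Unused.
#' @return A ggplot marking the apex and the baseline window.
#' @export
autoplot.chromatogram <- function(object, ...) {
  ggplot2::ggplot(object$trace,
                  ggplot2::aes(.data$time_min, .data$intensity)) +
    ggplot2::annotate("rect",
                      xmin = object$baseline_window[1],
                      xmax = object$baseline_window[2],
                      ymin = -Inf, ymax = Inf,
                      alpha = 0.1, fill = "steelblue") +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$peak_apex_time,
                        linetype = "dashed", colour = "grey50") +
    ggplot2::labs(x = "Time (min)", y = "Intensity (counts)")
}
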