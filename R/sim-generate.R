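#' Simulate calibration-standard peak-area ratios
#'
#' Generates analyte:IS peak-area ratios for each nominal level of the
#' configuration under the proportional-error model
#' `ratio = (slope * level + intercept) * (1 + e)`, `e ~ Normal(0, cv)`.
#'
#' @param config A [sim_assay_config()].
#' @param seed Optional seed overriding `config$seed`.
#'
#' @return A tibble with columns `level_ng_per_ml`, `replicate`, `set`
#'   (`"standard"`) and `area_ratio`.
#' @export
#' @examples
#' cfg <- sim_assay_config(proportional_cv = 0, n_replicates = 1, seed = 1)
#' simulate_calibration_areas(cfg)
simulate_calibration_areas <- function(config, seed = NULL) {
  stopifnot(inherits(config, "sim_assay_config"))
  maybe_set_seed(seed %||% config$seed)
  out <- tidyr::expand_grid(
    level_ng_per_ml = config$levels,
    replicate = seq_len(config$n_replicates)
  )
  truth <- config$true_slope * out$level_ng_per_ml + config$true_intercept
  eps <- rnorm(nrow(out), mean = 0, sd = config$proportional_cv)
  out$set <- "standard"
  out$area_ratio <- truth * (1 + eps)
  out[, c("level_ng_per_ml", "replicate", "set", "area_ratio")]
}

#' Simulate a Matuszewski three-set matrix-effect experiment
#'
#' Generates per-replicate peak areas for the three-set design used to
#' partition ionization suppression from extraction loss: set 1 is the neat
#' solution, set 2 the blank-matrix extract spiked after extraction, set 3
#' the matrix spiked before extraction. Ground truth:
#' `mean(set2)/mean(set1) -> suppression_factor` and
#' `mean(set3)/mean(set2) -> extraction_recovery` as replication grows.
#' Areas are generated for the analyte at every level and for the internal
#' standard (`level_ng_per_ml = NA`) with its own suppression/recovery truth.
#'
#' @param config A [sim_assay_config()]; `n_replicates` must be >= 2 so that
#'   a CV is defined downstream.
#' @param seed Optional seed overriding `config$seed`.
#'
#' @return A tibble with columns `analyte` (`"analyte"` or `"is"`),
#'   `level_ng_per_ml`, `set` (`"set1"`, `"set2"`, `"set3"`), `replicate`,
#'   `area`.
#' @seealso [matrix_effect()], [recovery()], [process_efficiency()],
#'   [matuszewski_summary()]
#' @export
simulate_matuszewski <- function(config, seed = NULL) {
  stopifnot(inherits(config, "sim_assay_config"))
  if (config$n_replicates < 2L) {
    abort("`n_replicates` must be >= 2 for a Matuszewski experiment (CV undefined otherwise).")
  }
  maybe_set_seed(seed %||% config$seed)

  grid <- dplyr::bind_rows(
    tidyr::expand_grid(
      analyte = "analyte",
      level_ng_per_ml = config$levels,
      set = c("set1", "set2", "set3"),
      replicate = seq_len(config$n_replicates)
    ),
    tidyr::expand_grid(
      analyte = "is",
      level_ng_per_ml = NA_real_,
      set = c("set1", "set2", "set3"),
      replicate = seq_len(config$n_replicates)
    )
  )

  neat <- ifelse(grid$analyte == "analyte",
                 config$base_area * grid$level_ng_per_ml,
                 config$is_base_area)
  supp <- ifelse(grid$analyte == "analyte",
                 config$suppression_factor, config$is_suppression_factor)
  rec <- ifelse(grid$analyte == "analyte",
                config$extraction_recovery, config$is_extraction_recovery)
  mean_area <- neat * dplyr::case_when(
    grid$set == "set1" ~ 1,
    grid$set == "set2" ~ supp,
    grid$set == "set3" ~ supp * rec
  )
  grid$area <- mean_area * (1 + rnorm(nrow(grid), 0, config$proportional_cv))
  as_tibble(grid)
}

#' Simulate a first-order decay time course
#'
#' Percent-remaining values under first-order loss,
#' `pct(t) = 100 * exp(-ln(2) * t / t_half) * (1 + e)`, `e ~ Normal(0, cv)`.
#' The zero-time sample is a measured value (it carries noise too), matching
#' how plasma and microsomal stability incubations are actually sampled.
#'
#' @param t_half True half-life (min), > 0.
#' @param times Sampling times (min), all >= 0. Defaults to the 7-point
#'   stability schedule 0, 15, 30, 60, 120, 360, 480 min.
#' @param residual_cv Proportional noise CV (default 0).
#' @param n_replicates Replicates per time point.
#' @param matrix Free-text label for the incubation matrix.
#' @param seed Integer seed (required when `residual_cv > 0`).
#'
#' @return A tibble with columns `matrix`, `replicate`, `time_min`,
#'   `pct_remaining`.
#' @seealso [fit_ke()]
#' @export
#' @examples
#' simulate_decay(t_half = 44, residual_cv = 0)
simulate_decay <- function(t_half,
                           times = c(0, 15, 30, 60, 120, 360, 480),
                           residual_cv = 0,
                           n_replicates = 1,
                           matrix = "unspecified",
                           seed = NULL) {
  assert_number(t_half, "t_half", lower = 0, strict_lower = TRUE)
  if (!is.numeric(times) || length(times) < 1L) abort("`times` must be numeric.")
  if (any(times < 0)) abort("Sampling times must be non-negative.")
  assert_number(residual_cv, "residual_cv", lower = 0, upper = 0.999)
  assert_number(n_replicates, "n_replicates", lower = 1)
  if (residual_cv > 0 && is.null(seed)) {
    abort("`seed` is required when `residual_cv` > 0.")
  }
  maybe_set_seed(seed)

  out <- tidyr::expand_grid(
    matrix = matrix,
    replicate = seq_len(as.integer(n_replicates)),
    time_min = sort(times)
  )
  truth <- 100 * exp(-log(2) * out$time_min / t_half)
  out$pct_remaining <- truth * (1 + rnorm(nrow(out), 0, residual_cv))
  out
}

# closed-form concentration solutions ---------------------------------------

# one-compartment IV bolus, dose in mg/kg, V mL/kg, CL mL/h/kg -> ng/mL
conc_one_cpt_iv <- function(t, dose, V, CL) {
  ke <- CL / V
  (dose * 1e6 / V) * exp(-ke * t)
}

# Bateman function (first-order absorption into a one-compartment model)
conc_one_cpt_oral <- function(t, dose, V, CL, ka, F_true) {
  ke <- CL / V
  if (isTRUE(all.equal(ka, ke))) {
    abort("`ka` equals `ke`; the Bateman form is singular. Use the limiting expression or perturb a parameter.")
  }
  (F_true * dose * 1e6 * ka) / (V * (ka - ke)) * (exp(-ke * t) - exp(-ka * t))
}

# two-compartment IV bolus, micro-constant parameterization
conc_two_cpt_iv <- function(t, dose, V1, k10, k12, k21) {
  mr <- macro_rates(k10, k12, k21)
  alpha <- mr[["alpha"]]; beta <- mr[["beta"]]
  A <- (dose * 1e6 / V1) * (alpha - k21) / (alpha - beta)
  B <- (dose * 1e6 / V1) * (k21 - beta) / (alpha - beta)
  A * exp(-alpha * t) + B * exp(-beta * t)
}

# two-compartment, first-order absorption into the central compartment
conc_two_cpt_oral <- function(t, dose, V1, k10, k12, k21, ka, F_true) {
  mr <- macro_rates(k10, k12, k21)
  alpha <- mr[["alpha"]]; beta <- mr[["beta"]]
  if (isTRUE(all.equal(ka, alpha)) || isTRUE(all.equal(ka, beta))) {
    abort("`ka` coincides with a macro rate constant; the oral solution is singular.")
  }
  k <- (F_true * dose * 1e6 * ka) / V1
  k * ((k21 - alpha) / ((ka - alpha) * (beta - alpha)) * exp(-alpha * t) +
       (k21 - beta) / ((ka - beta) * (alpha - beta)) * exp(-beta * t) +
       (k21 - ka) / ((alpha - ka) * (beta - ka)) * exp(-ka * t))
}

# noise-free model prediction for a pk config (optionally with subject-level
# CL/V multipliers)
predict_conc <- function(config, times, cl_mult = 1, v_mult = 1) {
  V <- config$V * v_mult
  CL <- config$CL * cl_mult
  if (config$model == "one_compartment") {
    if (config$route == "iv_bolus") {
      conc_one_cpt_iv(times, config$dose, V, CL)
    } else {
      conc_one_cpt_oral(times, config$dose, V, CL, config$ka, config$F_true)
    }
  } else {
    k10 <- CL / V
    if (config$route == "iv_bolus") {
      conc_two_cpt_iv(times, config$dose, V, k10, config$k12, config$k21)
    } else {
      conc_two_cpt_oral(times, config$dose, V, k10, config$k12, config$k21,
                        config$ka, config$F_true)
    }
  }
}

#' Simulate concentration-time profiles
#'
#' Draws per-subject concentration-time profiles from the closed-form
#' compartmental solution of the configuration, applies multiplicative
#' lognormal residual error (parameterized by `residual_cv`; the log-scale SD
#' is `sqrt(log(1 + cv^2))` so the residual CV equals the nominal value), and
#' flags observations below the LLOQ rather than censoring them, so that BLQ
#' policies can be exercised downstream.
#'
#' @param config A [sim_pk_config()].
#' @param seed Optional seed overriding `config$seed`.
#'
#' @return A tibble with columns `subject`, `route`, `dose_mg_per_kg`,
#'   `time_h`, `conc_ng_per_ml`, `blq_flag`.
#' @seealso [nca()], [pk_preset()]
#' @export
simulate_profile <- function(config, seed = NULL) {
  stopifnot(inherits(config, "sim_pk_config"))
  maybe_set_seed(seed %||% config$seed)

  sdlog <- lognormal_sdlog(config$residual_cv)
  purrr::map_dfr(seq_len(config$n_subjects), function(subj) {
    cl_mult <- if (config$bsv_cv_cl > 0)
      exp(rnorm(1, 0, lognormal_sdlog(config$bsv_cv_cl))) else 1
    v_mult <- if (config$bsv_cv_v > 0)
      exp(rnorm(1, 0, lognormal_sdlog(config$bsv_cv_v))) else 1
    truth <- predict_conc(config, config$sampling_times, cl_mult, v_mult)
    obs <- if (config$residual_cv > 0) {
      truth * exp(rnorm(length(truth), 0, sdlog))
    } else truth
    tibble(
      subject = subj,
      route = config$route,
      dose_mg_per_kg = config$dose,
      time_h = config$sampling_times,
      conc_ng_per_ml = obs,
      blq_flag = obs < config$lloq
    )
  })
}

#' Simulate a chromatographic trace
#'
#' A Gaussian analyte peak on a flat baseline with white detector noise,
#' sampled on a regular time grid. A constant baseline offset (default five
#' noise SDs) keeps intensities positive; [signal_to_noise()] subtracts the
#' baseline mean, so the offset does not affect the S/N ratio.
#'
#' @param peak_height Apex height above baseline (counts), >= 0.
#' @param peak_sd Gaussian peak SD (min), > 0.
#' @param noise_sd Baseline white-noise SD (counts), >= 0.
#' @param grid Regular time grid (min), non-empty with constant spacing.
#' @param peak_apex_time Apex position (min).
#' @param baseline_window Two-element `(t_start, t_end)` window used for the
#'   baseline statistics; must not overlap the peak support
#'   (apex +/- 5 peak SDs).
#' @param baseline_level Constant baseline offset (counts); defaults to
#'   `5 * noise_sd`.
#' @param seed Integer seed (required when `noise_sd > 0`).
#'
#' @return An object of class `chromatogram`: a list with a `trace` tibble
#'   (`time_min`, `intensity`) plus `peak_apex_time` and `baseline_window`.
#' @seealso [signal_to_noise()]
#' @export
simulate_chromatogram <- function(peak_height,
                                  peak_sd = 0.05,
                                  noise_sd = 0,
                                  grid = seq(0, 6, by = 0.002),
                                  peak_apex_time = 3.7,
                                  baseline_window = c(0, 2),
                                  baseline_level = 5 * noise_sd,
                                  seed = NULL) {
  assert_number(peak_height, "peak_height", lower = 0)
  assert_number(peak_sd, "peak_sd", lower = 0, strict_lower = TRUE)
  assert_number(noise_sd, "noise_sd", lower = 0)
  if (length(grid) < 2L) abort("`grid` must contain at least two time points.")
  spacing <- diff(grid)
  if (any(abs(spacing - spacing[1]) > 1e-9 * max(abs(spacing)))) {
    abort("`grid` must be regularly spaced.")
  }
  if (length(baseline_window) != 2L || baseline_window[2] <= baseline_window[1]) {
    abort("`baseline_window` must be an increasing (t_start, t_end) pair.")
  }
  support <- peak_apex_time + c(-5, 5) * peak_sd
  if (baseline_window[1] < support[2] && baseline_window[2] > support[1]) {
    abort("`baseline_window` overlaps the peak support; choose a peak-free region.")
  }
  if (noise_sd > 0 && is.null(seed)) abort("`seed` is required when `noise_sd` > 0.")
  maybe_set_seed(seed)

  signal <- peak_height * exp(-(grid - peak_apex_time)^2 / (2 * peak_sd^2))
  noise <- if (noise_sd > 0) rnorm(length(grid), 0, noise_sd) else 0
  intensity <- pmax(0, baseline_level + signal + noise)
  structure(
    list(
      trace = tibble(time_min = grid, intensity = intensity),
      peak_apex_time = peak_apex_time,
      baseline_window = baseline_window
    ),
    class = "chromatogram"
  )
}

#' @export
print.chromatogram <- function(x, ...) {
  cat("<chromatogram>\n")
  cat(sprintf("  %d points over %.3g-%.3g min, apex at %.3g min\n",
              nrow(x$trace), min(x$trace$time_min), max(x$trace$time_min),
              x$peak_apex_time))
  cat(sprintf("  baseline window: %.3g-%.3g min\n",
              x$baseline_window[1], x$baseline_window[2]))
  invisible(x)
}
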