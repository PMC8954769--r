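#' Configuration for the synthetic assay-response generator
#'
#' Bundles the ground-truth parameters of a simulated LC-MS/MS assay: the
#' true calibration line mapping concentration to analyte:IS peak-area ratio,
#' a proportional (constant-CV) response error, and the matrix-effect /
#' extraction-recovery truth used by [simulate_matuszewski()].
#'
#' The defaults mirror the validated assay this package models: a calibration
#' line of slope 0.001310 per (ng/mL) and intercept 0.000042 over
#' 2--3000 ng/mL, replicate CVs in the mid single digits, 70--80% ionization
#' suppression (matrix effect below 100%) and essentially complete
#' protein-precipitation extraction recovery.
#'
#' @param true_slope True calibration slope, response per (ng/mL).
#' @param true_intercept True calibration intercept (dimensionless area ratio).
#' @param proportional_cv Proportional error CV of replicate responses,
#'   fraction in `[0, 1)`.
#' @param levels Nominal concentrations (ng/mL), all > 0.
#' @param n_replicates Replicates per level (>= 1; >= 2 for Matuszewski sets).
#' @param suppression_factor True matrix-effect fraction (set 2 / set 1),
#'   in (0, 1].
#' @param extraction_recovery True extraction-recovery fraction
#'   (set 3 / set 2), in (0, 1.2].
#' @param is_suppression_factor,is_extraction_recovery Truths for the internal
#'   standard; default to the analyte values.
#' @param base_area Neat-solution analyte peak area per (ng/mL) of nominal
#'   concentration (arbitrary counts).
#' @param is_base_area Neat-solution internal-standard peak area (counts).
#' @param seed Integer seed; every generator call is reproducible under it.
#'
#' @return An object of class `sim_assay_config`.
#' @seealso [simulate_calibration_areas()], [simulate_matuszewski()]
#' @export
#' @examples
#' cfg <- sim_assay_config(proportional_cv = 0, seed = 1)
#' simulate_calibration_areas(cfg)
sim_assay_config <- function(true_slope = 0.001310,
                             true_intercept = 0.000042,
                             proportional_cv = 0.06,
                             levels = c(2, 3, 10, 100, 1000, 2000, 3000),
                             n_replicates = 5,
                             suppression_factor = 0.75,
                             extraction_recovery = 1.0,
                             is_suppression_factor = suppression_factor,
                             is_extraction_recovery = extraction_recovery,
                             base_area = 1e5,
                             is_base_area = 5e5,
                             seed = NULL) {
  assert_number(true_slope, "true_slope", lower = 0, strict_lower = TRUE)
  assert_number(true_intercept, "true_intercept")
  assert_number(proportional_cv, "proportional_cv", lower = 0, upper = 0.999)
  if (!is.numeric(levels) || length(levels) < 1L || any(!is.finite(levels))) {
    abort("`levels` must be a numeric vector of nominal concentrations.")
  }
  if (any(levels <= 0)) {
    abort("All nominal concentrations in `levels` must be > 0.")
  }
  assert_number(n_replicates, "n_replicates", lower = 1)
  assert_number(suppression_factor, "suppression_factor",
                lower = 0, upper = 1, strict_lower = TRUE)
  assert_number(extraction_recovery, "extraction_recovery",
                lower = 0, upper = 1.2, strict_lower = TRUE)
  assert_number(is_suppression_factor, "is_suppression_factor",
                lower = 0, upper = 1, strict_lower = TRUE)
  assert_number(is_extraction_recovery, "is_extraction_recovery",
                lower = 0, upper = 1.2, strict_lower = TRUE)
  assert_number(base_area, "base_area", lower = 0, strict_lower = TRUE)
  assert_number(is_base_area, "is_base_area", lower = 0, strict_lower = TRUE)
  if (is.null(seed)) abort("`seed` is required: every simulation is seeded.")

  structure(
    list(
      true_slope = true_slope,
      true_intercept = true_intercept,
      proportional_cv = proportional_cv,
      levels = sort(unique(levels)),
      n_replicates = as.integer(n_replicates),
      suppression_factor = suppression_factor,
      extraction_recovery = extraction_recovery,
      is_suppression_factor = is_suppression_factor,
      is_extraction_recovery = is_extraction_recovery,
      base_area = base_area,
      is_base_area = is_base_area,
      seed = as.integer(seed)
    ),
    class = "sim_assay_config"
  )
}

#' Configuration for the synthetic concentration-time profile generator
#'
#' Describes a compartmental ground-truth model (one- or two-compartment,
#' IV bolus or first-order oral absorption), the sampling design, a
#' multiplicative lognormal residual error, optional between-subject
#' variability, and the quantitation limit used to flag BLQ observations.
#'
#' Units follow the bioanalytical convention throughout: dose in mg/kg,
#' volumes in mL/kg, clearance in mL/h/kg, rate constants in 1/h, times in h,
#' concentrations in ng/mL. With dose in mg/kg and volume in mL/kg,
#' dose/volume is in (mg/mL) * 1e6 = ng/mL.
#'
#' @param model `"one_compartment"` or `"two_compartment"`.
#' @param route `"iv_bolus"` or `"oral"`.
#' @param dose Dose in mg/kg, > 0.
#' @param V Central volume of distribution (mL/kg) -- one-compartment (also
#'   accepted as the central volume `V1` of the two-compartment model).
#' @param CL Total clearance (mL/h/kg). For the two-compartment model either
#'   `CL` or `k10` may be given (`k10 = CL/V`).
#' @param k10,k12,k21 Two-compartment micro rate constants (1/h).
#' @param ka First-order absorption rate constant (1/h); oral route only.
#' @param F_true True absolute bioavailability fraction in (0, 1]; oral only.
#' @param sampling_times Strictly increasing sampling times (h), all >= 0.
#' @param residual_cv CV of the multiplicative lognormal residual error.
#' @param lloq Lower limit of quantification (ng/mL); simulated values below
#'   it are emitted but flagged BLQ.
#' @param n_subjects Number of subjects to simulate.
#' @param bsv_cv_cl,bsv_cv_v Between-subject lognormal CVs on clearance and
#'   volume (default 0: all subjects share the ground truth).
#' @param allow_flip_flop If `TRUE`, permit oral absorption slower than
#'   elimination (flip-flop kinetics) instead of rejecting the configuration.
#' @param seed Integer seed.
#'
#' @return An object of class `sim_pk_config`.
#' @seealso [simulate_profile()], [pk_preset()]
#' @export
#' @examples
#' cfg <- sim_pk_config(route = "iv_bolus", dose = 2, V = 1000, CL = 100,
#'                      residual_cv = 0, seed = 1)
#' simulate_profile(cfg)
sim_pk_config <- function(model = c("one_compartment", "two_compartment"),
                          route = c("iv_bolus", "oral"),
                          dose,
                          V = NULL, CL = NULL,
                          k10 = NULL, k12 = NULL, k21 = NULL,
                          ka = NULL, F_true = 1,
                          sampling_times = c(0.083, 0.25, 0.5, 1, 2, 4, 6, 8, 24, 48),
                          residual_cv = 0.1,
                          lloq = 2,
                          n_subjects = 4,
                          bsv_cv_cl = 0, bsv_cv_v = 0,
                          allow_flip_flop = FALSE,
                          seed = NULL) {
  model <- match.arg(model)
  route <- match.arg(route)
  assert_number(dose, "dose", lower = 0, strict_lower = TRUE)
  assert_number(V, "V", lower = 0, strict_lower = TRUE)
  if (model == "one_compartment") {
    assert_number(CL, "CL", lower = 0, strict_lower = TRUE)
    k10 <- CL / V
  } else {
    if (is.null(k10)) {
      assert_number(CL, "CL", lower = 0, strict_lower = TRUE)
      k10 <- CL / V
    } else {
      assert_number(k10, "k10", lower = 0, strict_lower = TRUE)
      CL <- CL %||% (k10 * V)
    }
    assert_number(k12, "k12", lower = 0, strict_lower = TRUE)
    assert_number(k21, "k21", lower = 0, strict_lower = TRUE)
  }
  if (!is.numeric(sampling_times) || length(sampling_times) < 2L) {
    abort("`sampling_times` must be a numeric vector of at least two times.")
  }
  if (any(sampling_times < 0) || any(diff(sampling_times) <= 0)) {
    abort("`sampling_times` must be non-negative and strictly increasing.")
  }
  assert_number(residual_cv, "residual_cv", lower = 0, upper = 0.999)
  assert_number(lloq, "lloq", lower = 0)
  assert_number(n_subjects, "n_subjects", lower = 1)
  assert_number(bsv_cv_cl, "bsv_cv_cl", lower = 0, upper = 0.999)
  assert_number(bsv_cv_v, "bsv_cv_v", lower = 0, upper = 0.999)
  if (route == "oral") {
    assert_number(ka, "ka", lower = 0, strict_lower = TRUE)
    assert_number(F_true, "F_true", lower = 0, upper = 1, strict_lower = TRUE)
    ke <- if (model == "one_compartment") k10 else slow_macro_rate(k10, k12, k21)
    if (isTRUE(all.equal(ka, ke))) {
      abort(paste0(
        "`ka` equals the elimination rate constant; the first-order oral ",
        "solution is singular there. Perturb `ka` or use the limiting ",
        "(ka -> ke) expression."
      ))
    }
    if (ka <= ke && !allow_flip_flop) {
      abort(paste0(
        "`ka` <= elimination rate constant implies flip-flop kinetics; set ",
        "`allow_flip_flop = TRUE` if intended."
      ))
    }
  }
  if (is.null(seed)) abort("`seed` is required: every simulation is seeded.")

  structure(
    list(
      model = model, route = route, dose = dose,
      V = V, CL = CL, k10 = k10, k12 = k12, k21 = k21,
      ka = ka, F_true = F_true,
      sampling_times = sampling_times,
      residual_cv = residual_cv, lloq = lloq,
      n_subjects = as.integer(n_subjects),
      bsv_cv_cl = bsv_cv_cl, bsv_cv_v = bsv_cv_v,
      allow_flip_flop = allow_flip_flop,
      seed = as.integer(seed)
    ),
    class = "sim_pk_config"
  )
}

# the slower (terminal) macro rate constant of the two-compartment model
slow_macro_rate <- function(k10, k12, k21) {
  s <- k10 + k12 + k21
  p <- k10 * k21
  (s - sqrt(s^2 - 4 * p)) / 2
}

macro_rates <- function(k10, k12, k21) {
  s <- k10 + k12 + k21
  p <- k10 * k21
  disc <- sqrt(s^2 - 4 * p)
  c(alpha = (s + disc) / 2, beta = (s - disc) / 2)
}

#' Demonstration pharmacokinetic presets
#'
#' One-compartment presets whose clearance and steady-state volume match the
#' magnitudes reported for the PROTAC degrader ARV-110 in rats and mice
#' (CL 413.6 / 180.9 mL/h/kg, Vss 5775 / 2366 mL/kg; IV 2 mg/kg, PO 5 mg/kg)
#' together with the corresponding sparse in vivo sampling schedules. These
#' are illustrative presets, not fits to any animal data: oral `ka` is chosen
#' so the simulated Tmax falls near the reported 4.8--5.5 h, and `F_true`
#' matches the reported bioavailability.
#'
#' @param name One of `"rat_iv"`, `"rat_oral"`, `"mouse_iv"`, `"mouse_oral"`.
#' @param seed Integer seed stored in the returned configuration.
#' @param residual_cv Residual error CV (default 0.10).
#' @param n_subjects Cohort size (default 4, the reported group size).
#'
#' @return A [sim_pk_config()] object.
#' @export
#' @examples
#' simulate_profile(pk_preset("rat_iv", seed = 7))
pk_preset <- function(name = c("rat_iv", "rat_oral", "mouse_iv", "mouse_oral"),
                      seed = 1, residual_cv = 0.10, n_subjects = 4) {
  name <- match.arg(name)
  rat_times_iv <- c(0.083, 0.25, 0.5, 1, 2, 4, 6, 8, 24, 48)
  rat_times_po <- c(0.25, 0.5, 1, 2, 4, 6, 8, 24, 48)
  mouse_times_iv <- c(0.05, 0.12, 0.5, 1, 2, 4, 8, 24, 48)
  mouse_times_po <- c(0.12, 0.5, 1, 2, 4, 8, 24, 48)
  switch(name,
    rat_iv = sim_pk_config(
      model = "one_compartment", route = "iv_bolus", dose = 2,
      V = 5775, CL = 413.6, sampling_times = rat_times_iv,
      residual_cv = residual_cv, lloq = 2, n_subjects = n_subjects, seed = seed
    ),
    rat_oral = sim_pk_config(
      model = "one_compartment", route = "oral", dose = 5,
      V = 5775, CL = 413.6, ka = 0.37, F_true = 0.2383,
      sampling_times = rat_times_po,
      residual_cv = residual_cv, lloq = 2, n_subjects = n_subjects, seed = seed
    ),
    mouse_iv = sim_pk_config(
      model = "one_compartment", route = "iv_bolus", dose = 2,
      V = 2366, CL = 180.9, sampling_times = mouse_times_iv,
      residual_cv = residual_cv, lloq = 2, n_subjects = n_subjects, seed = seed
    ),
    mouse_oral = sim_pk_config(
      model = "one_compartment", route = "oral", dose = 5,
      V = 2366, CL = 180.9, ka = 0.44, F_true = 0.3789,
      sampling_times = mouse_times_po,
      residual_cv = residual_cv, lloq = 2, n_subjects = n_subjects, seed = seed
    )
  )
}

#' @export
print.sim_assay_config <- function(x, ...) {
  cat("<sim_assay_config>\n")
  cat(sprintf("  true line: ratio = %.6g * conc + %.6g\n",
              x$true_slope, x$true_intercept))
  cat(sprintf("  levels (ng/mL): %s  x%d replicates\n",
              paste(x$levels, collapse = ", "), x$n_replicates))
  cat(sprintf("  proportional CV: %.3g  suppression: %.3g  recovery: %.3g\n",
              x$proportional_cv, x$suppression_factor, x$extraction_recovery))
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}

#' @export
print.sim_pk_config <- function(x, ...) {
  cat("<sim_pk_config>\n")
  cat(sprintf("  %s, %s, dose %.3g mg/kg\n", x$model, x$route, x$dose))
  cat(sprintf("  V = %.4g mL/kg, CL = %.4g mL/h/kg", x$V, x$CL))
  if (!is.null(x$k12)) cat(sprintf(", k12 = %.3g, k21 = %.3g /h", x$k12, x$k21))
  if (!is.null(x$ka)) cat(sprintf(", ka = %.3g /h, F = %.3g", x$ka, x$F_true))
  cat("\n")
  cat(sprintf("  %d subjects, residual CV %.3g, LLOQ %.3g ng/mL, seed %d\n",
              x$n_subjects, x$residual_cv, x$lloq, x$seed))
  invisible(x)
}
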