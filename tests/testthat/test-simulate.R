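test_that("noise-free calibration responses follow the true line exactly", {
  cfg <- sim_assay_config(true_slope = 0.001310, true_intercept = 0.000042,
                          proportional_cv = 0, n_replicates = 1, seed = 1)
  out <- simulate_calibration_areas(cfg)
  expect_equal(out$area_ratio, 0.001310 * out$level_ng_per_ml + 0.000042)
  expect_equal(out$area_ratio[out$level_ng_per_ml == 100], 0.131042)
})

test_that("invalid assay configurations are rejected", {
  expect_error(sim_assay_config(levels = c(0, 100), seed = 1), "must be > 0")
  expect_error(sim_assay_config(levels = c(-5, 100), seed = 1), "must be > 0")
  expect_error(sim_assay_config(suppression_factor = 0, seed = 1))
  expect_error(sim_assay_config(proportional_cv = -0.1, seed = 1))
  expect_error(sim_assay_config(seed = NULL), "seed")
})

test_that("replicate CV converges to the configured proportional CV", {
  cfg <- sim_assay_config(proportional_cv = 0.05, levels = 100,
                          n_replicates = 10000, seed = 42)
  out <- simulate_calibration_areas(cfg)
  emp_cv <- sd(out$area_ratio) / mean(out$area_ratio)
  # Monte-Carlo SE of a CV estimate is ~ cv / sqrt(2 n)
  mc_se <- 0.05 / sqrt(2 * 10000)
  expect_lt(abs(emp_cv - 0.05), 3 * mc_se)
})

test_that("simulation is bit-identical under a fixed seed and config", {
  cfg <- sim_assay_config(seed = 7)
  expect_identical(simulate_calibration_areas(cfg), simulate_calibration_areas(cfg))
  expect_identical(simulate_matuszewski(cfg), simulate_matuszewski(cfg))
  pk <- pk_preset("mouse_oral", seed = 7)
  expect_identical(simulate_profile(pk), simulate_profile(pk))
  expect_identical(
    simulate_decay(44, residual_cv = 0.05, n_replicates = 3, seed = 7),
    simulate_decay(44, residual_cv = 0.05, n_replicates = 3, seed = 7)
  )
})

test_that("Matuszewski sets encode the suppression and recovery truths", {
  noise_free <- sim_assay_config(proportional_cv = 0, n_replicates = 3,
                                 suppression_factor = 0.70,
                                 extraction_recovery = 1.00, seed = 1)
  sets <- simulate_matuszewski(noise_free)
  me <- matrix_effect(sets); rec <- recovery(sets); pe <- process_efficiency(sets)
  expect_equal(me$me_pct, rep(70, nrow(me)))
  expect_equal(rec$recovery_pct, rep(100, nrow(rec)))
  expect_equal(pe$pe_pct, rep(70, nrow(pe)))

  identity_cfg <- sim_assay_config(proportional_cv = 0, n_replicates = 3,
                                   suppression_factor = 1, extraction_recovery = 1,
                                   seed = 1)
  sets_id <- simulate_matuszewski(identity_cfg)
  expect_equal(matrix_effect(sets_id)$me_pct, rep(100, 8))
  expect_equal(recovery(sets_id)$recovery_pct, rep(100, 8))
  expect_equal(process_efficiency(sets_id)$pe_pct, rep(100, 8))

  expect_error(
    simulate_matuszewski(sim_assay_config(n_replicates = 1, seed = 1)),
    "CV undefined"
  )
})

test_that("matrix effect converges to the generative suppression at large n", {
  cfg <- sim_assay_config(proportional_cv = 0.05, levels = 5,
                          n_replicates = 10000,
                          suppression_factor = 0.6757,
                          extraction_recovery = 1.056, seed = 11)
  sets <- simulate_matuszewski(cfg)
  me <- matrix_effect(sets)
  # ratio-of-means SE ~ truth * cv * sqrt(2/n), on the percent scale
  mc_se <- 67.57 * 0.05 * sqrt(2 / 10000)
  expect_lt(abs(me$me_pct[me$analyte == "analyte"] - 67.57), 3 * mc_se)
})

test_that("first-order decay generator matches its closed form", {
  expect_equal(
    simulate_decay(60, times = c(0, 60), residual_cv = 0)$pct_remaining,
    c(100, 50)
  )
  out44 <- simulate_decay(44, times = 120, residual_cv = 0)
  expect_equal(out44$pct_remaining, 100 * exp(-log(2) * 120 / 44))
  expect_equal(round(out44$pct_remaining, 2), 15.10)
  expect_error(simulate_decay(44, times = c(-1, 10)), "non-negative")
  expect_error(simulate_decay(0, times = c(0, 10)), "t_half")
})

test_that("IV bolus profile starts at dose over volume", {
  cfg <- sim_pk_config(route = "iv_bolus", dose = 2, V = 1000, CL = 100,
                       sampling_times = c(0, 1, 2, 4, 8),
                       residual_cv = 0, seed = 1)
  prof <- simulate_profile(cfg)
  expect_equal(prof$conc_ng_per_ml[prof$time_h == 0], rep(2000, 4))
})

test_that("oral profile peaks at the Bateman maximum", {
  V <- 5775; CL <- 413.6; ka <- 0.37
  ke <- CL / V
  tmax_true <- log(ka / ke) / (ka - ke)
  cfg <- sim_pk_config(route = "oral", dose = 5, V = V, CL = CL, ka = ka,
                       F_true = 0.25,
                       sampling_times = seq(0.01, 48, by = 0.01),
                       residual_cv = 0, n_subjects = 1, seed = 1)
  prof <- simulate_profile(cfg)
  tmax_obs <- prof$time_h[which.max(prof$conc_ng_per_ml)]
  expect_lt(abs(tmax_obs - tmax_true), 0.011)
})

test_that("oral absorption equal to elimination is rejected as singular", {
  expect_error(
    sim_pk_config(route = "oral", dose = 5, V = 1000, CL = 100, ka = 0.1,
                  sampling_times = c(0.5, 1, 2), residual_cv = 0, seed = 1),
    "singular|limiting"
  )
  expect_error(
    sim_pk_config(route = "oral", dose = 5, V = 1000, CL = 100, ka = 0.05,
                  sampling_times = c(0.5, 1, 2), residual_cv = 0, seed = 1),
    "flip-flop"
  )
  expect_s3_class(
    sim_pk_config(route = "oral", dose = 5, V = 1000, CL = 100, ka = 0.05,
                  sampling_times = c(0.5, 1, 2), residual_cv = 0,
                  allow_flip_flop = TRUE, seed = 1),
    "sim_pk_config"
  )
})

test_that("oral profile integrates to F * Dose / CL", {
  V <- 2366; CL <- 180.9; F_true <- 0.3789; dose <- 5
  ke <- CL / V
  horizon <- 12 * log(2) / ke  # well past seven elimination half-lives
  cfg <- sim_pk_config(route = "oral", dose = dose, V = V, CL = CL, ka = 0.44,
                       F_true = F_true,
                       sampling_times = seq(0, horizon, length.out = 4000),
                       residual_cv = 0, n_subjects = 1, seed = 1)
  prof <- simulate_profile(cfg)
  auc <- auc_aumc(prof$time_h, prof$conc_ng_per_ml, method = "linear")$auc_last
  truth <- F_true * dose * 1e6 / CL
  expect_lt(abs(auc - truth) / truth, 0.005)
})

test_that("two-compartment closed forms agree with an ODE solver oracle", {
  skip_if_not_installed("deSolve")
  k10 <- 0.08; k12 <- 0.3; k21 <- 0.15; V1 <- 2000; dose <- 2
  times <- c(0, 0.25, 0.5, 1, 2, 4, 8, 16, 24, 48)
  cfg <- sim_pk_config(model = "two_compartment", route = "iv_bolus",
                       dose = dose, V = V1, k10 = k10, k12 = k12, k21 = k21,
                       sampling_times = times, residual_cv = 0,
                       n_subjects = 1, seed = 1)
  prof <- simulate_profile(cfg)

  rhs <- function(t, y, p) {
    with(as.list(c(y, p)), list(c(
      -(k10 + k12) * A1 + k21 * A2,
      k12 * A1 - k21 * A2
    )))
  }
  ode <- deSolve::ode(y = c(A1 = dose * 1e6, A2 = 0), times = times,
                      func = rhs, parms = list(k10 = k10, k12 = k12, k21 = k21),
                      rtol = 1e-10, atol = 1e-10)
  expect_equal(prof$conc_ng_per_ml, ode[, "A1"] / V1, tolerance = 1e-7,
               ignore_attr = TRUE)

  # oral absorption into the central compartment
  ka <- 0.9
  cfg_po <- sim_pk_config(model = "two_compartment", route = "oral",
                          dose = dose, V = V1, k10 = k10, k12 = k12, k21 = k21,
                          ka = ka, F_true = 0.5,
                          sampling_times = times[-1], residual_cv = 0,
                          n_subjects = 1, seed = 1)
  prof_po <- simulate_profile(cfg_po)
  rhs_po <- function(t, y, p) {
    with(as.list(c(y, p)), list(c(
      -ka * Agut,
      ka * Agut - (k10 + k12) * A1 + k21 * A2,
      k12 * A1 - k21 * A2
    )))
  }
  ode_po <- deSolve::ode(y = c(Agut = 0.5 * dose * 1e6, A1 = 0, A2 = 0),
                         times = c(0, times[-1]), func = rhs_po,
                         parms = list(ka = ka, k10 = k10, k12 = k12, k21 = k21),
                         rtol = 1e-10, atol = 1e-10)
  expect_equal(prof_po$conc_ng_per_ml, ode_po[-1, "A1"] / V1, tolerance = 1e-7,
               ignore_attr = TRUE)
})

test_that("residual error is flagged against the LLOQ, not censored", {
  cfg <- pk_preset("rat_oral", seed = 5)
  prof <- simulate_profile(cfg)
  expect_true(all(c("conc_ng_per_ml", "blq_flag") %in% names(prof)))
  expect_identical(prof$blq_flag, prof$conc_ng_per_ml < cfg$lloq)
})

test_that("chromatogram simulator validates its inputs", {
  expect_error(simulate_chromatogram(100, peak_sd = 0), "peak_sd")
  expect_error(simulate_chromatogram(100, grid = numeric(0)), "grid")
  expect_error(simulate_chromatogram(100, grid = c(0, 1, 3)), "regularly spaced")
  expect_error(
    simulate_chromatogram(100, peak_sd = 0.5, peak_apex_time = 2,
                          baseline_window = c(0, 1.9)),
    "overlaps"
  )
})
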