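monoexp_profile <- function(c0 = 2525, ke = 0.05, times = c(0.083, 0.25, 0.5, 1, 2, 4, 6, 8, 24, 48)) {
  tibble::tibble(time_h = times, conc_ng_per_ml = c0 * exp(-ke * times))
}

test_that("Cmax and Tmax are read directly off the profile", {
  prof <- tibble::tibble(time_h = c(1, 2, 4, 8), conc = c(300, 500, 612, 100))
  expect_equal(cmax_tmax(prof$time_h, prof$conc), tibble::tibble(cmax = 612, tmax = 4))

  iv <- monoexp_profile()
  ct <- cmax_tmax(iv$time_h, iv$conc_ng_per_ml)
  expect_equal(ct$tmax, 0.083)

  tie <- cmax_tmax(c(1, 2, 3), c(10, 50, 50))
  expect_equal(tie$tmax, 2)  # earliest time wins the tie
})

test_that("terminal slope selection recovers an exact monoexponential tail", {
  iv <- monoexp_profile(ke = 0.05)
  lam <- select_lambda_z(iv$time_h, iv$conc_ng_per_ml, route = "iv_bolus")
  expect_equal(lam$lambda_z, 0.05, tolerance = 1e-10)
  expect_equal(lam$adj_r2, 1, tolerance = 1e-12)
  expect_equal(lam$n_lambda_points, nrow(iv))  # all eligible points selected

  rising <- tibble::tibble(time_h = 1:5, conc = c(1, 2, 4, 8, 16))
  expect_error(select_lambda_z(rising$time_h, rising$conc), "Terminal phase")
  expect_error(select_lambda_z(c(1, 2), c(10, 5)), "eligible")
})

test_that("lambda_z approaches the slow macro rate of a biexponential profile", {
  k10 <- 0.08; k12 <- 0.3; k21 <- 0.15; V1 <- 2000
  beta <- assaypk:::slow_macro_rate(k10, k12, k21)
  t_beta <- log(2) / beta
  times <- c(0.1, 0.25, 0.5, 1, 2, 4, seq(8, 4 * t_beta, length.out = 12))
  cfg <- sim_pk_config(model = "two_compartment", route = "iv_bolus", dose = 2,
                       V = V1, k10 = k10, k12 = k12, k21 = k21,
                       sampling_times = times, residual_cv = 0,
                       n_subjects = 1, seed = 1)
  prof <- simulate_profile(cfg)
  lam <- select_lambda_z(prof$time_h, prof$conc_ng_per_ml, route = "iv_bolus")
  expect_lt(abs(lam$lambda_z - beta) / beta, 0.02)
})

test_that("oral terminal windows exclude the Tmax point", {
  ke <- 0.07; ka <- 0.5
  times <- c(0.5, 1, 2, 4, 6, 8, 24, 48)
  conc <- 1000 * (exp(-ke * times) - exp(-ka * times))
  tmax <- times[which.max(conc)]
  lam <- select_lambda_z(times, conc, route = "oral")
  expect_gt(lam$lambda_z, 0)
  expect_gt(lam$lambda_z_start_time, tmax)
})

test_that("trapezoid AUC/AUMC match hand formulas and analytic integrals", {
  # constant concentration: both methods give rectangle area
  const <- auc_aumc(c(0, 1, 2, 4), rep(10, 4), method = "linear")
  expect_equal(const$auc_last, 40)
  const_ld <- auc_aumc(c(0, 1, 2, 4), rep(10, 4), method = "linear_up_log_down")
  expect_equal(const_ld$auc_last, 40)

  # two-point hand formulas
  lin <- auc_aumc(c(0, 1), c(100, 50), method = "linear")
  expect_equal(lin$auc_last, 75)
  ld <- auc_aumc(c(0, 1), c(100, 50), method = "linear_up_log_down")
  expect_equal(ld$auc_last, 50 / log(2), tolerance = 1e-12)
  expect_equal(round(ld$auc_last, 2), 72.13)

  # log-down is exact on a monoexponential decline; linear overestimates
  t <- seq(0, 40, by = 0.5)
  conc <- 100 * exp(-0.1 * t)
  truth <- analytic_auc_monoexp(100, 0.1, 40)
  ld2 <- auc_aumc(t, conc, method = "linear_up_log_down")
  lin2 <- auc_aumc(t, conc, method = "linear")
  expect_equal(ld2$auc_last, truth, tolerance = 1e-10)
  expect_gt(lin2$auc_last, truth)
  expect_equal(ld2$aumc_last, analytic_aumc_monoexp(100, 0.1, 40),
               tolerance = 1e-10)

  # log-down never exceeds linear on a strictly decreasing profile
  expect_lte(ld2$auc_last, lin2$auc_last)
  expect_error(auc_aumc(1, 10), "lengths|two")
})

test_that("extrapolation to infinity follows the tail formulas", {
  ext <- extrapolate(auc_last = 500, aumc_last = 4000, clast = 10, tlast = 24,
                     lambda_z = 0.1)
  expect_equal(ext$auc_inf, 600)  # tail area clast/lambda = 100
  expect_equal(ext$aumc_inf, 4000 + 10 * 24 / 0.1 + 10 / 0.01)
  expect_equal(ext$pct_extrapolated, 100 * 100 / 600)

  # clast -> 0 limit: no added area
  ext0 <- extrapolate(500, 4000, clast = 0, tlast = 24, lambda_z = 0.1)
  expect_equal(ext0$auc_inf, 500)

  expect_warning(extrapolate(100, 500, clast = 10, tlast = 2, lambda_z = 0.05),
                 "extrapolated")
  expect_error(extrapolate(100, 500, 10, 2, lambda_z = 0), "lambda_z")
})

test_that("IV dose over AUCinf gives clearance in mL/h/kg", {
  iv <- derive_iv_parameters(dose = 2, auc_inf = 4857, aumc_inf = 4857 * 10.16,
                             lambda_z = log(2) / 13.62)
  expect_equal(round(iv$cl, 1), 411.8)  # 2e6 / 4857
  expect_equal(iv$mrt, 10.16)
  expect_equal(iv$vss, iv$cl * iv$mrt)
  expect_equal(iv$t_half, 13.62)
})

test_that("noise-free dense one-compartment NCA recovers the generative truth", {
  dose <- rat_truth$dose; V <- rat_truth$V; CL <- rat_truth$CL
  ke <- CL / V
  times <- c(0, exp(seq(log(0.01), log(14 * log(2) / ke), length.out = 160)))
  cfg <- sim_pk_config(route = "iv_bolus", dose = dose, V = V, CL = CL,
                       sampling_times = times, residual_cv = 0,
                       n_subjects = 1, seed = 1)
  res <- nca(simulate_profile(cfg))
  expect_lt(abs(res$cl - CL) / CL, 0.005)
  expect_lt(abs(res$vss - V) / V, 0.005)
  expect_lt(abs(res$t_half - log(2) / ke) / (log(2) / ke), 0.005)
  # MRT of a monoexponential IV profile is 1/ke
  expect_lt(abs(res$mrt - 1 / ke) * ke, 0.005)
  # clearance times AUCinf returns the administered dose exactly
  expect_equal(res$cl * res$auc_inf, dose * 1e6, tolerance = 1e-9)
})

test_that("recovery error shrinks as sampling gets denser", {
  dose <- 2; V <- 1000; CL <- 100; ke <- CL / V
  err_for <- function(n_points) {
    times <- c(0, exp(seq(log(0.05), log(10 * log(2) / ke), length.out = n_points)))
    cfg <- sim_pk_config(route = "iv_bolus", dose = dose, V = V, CL = CL,
                         sampling_times = times, residual_cv = 0,
                         n_subjects = 1, seed = 1)
    res <- nca(simulate_profile(cfg), method = "linear")
    abs(res$cl - CL) / CL
  }
  errs <- vapply(c(10, 40, 160), err_for, numeric(1))
  expect_true(all(diff(errs) < 0))
})

test_that("BLQ policies zero leading values and drop trailing ones", {
  prof <- tibble::tibble(
    subject = 1, route = "oral", dose_mg_per_kg = 5,
    time_h = c(0.25, 0.5, 1, 2, 4, 8, 24, 48),
    conc_ng_per_ml = c(1, 20, 80, 100, 60, 30, 5, 0.5),
    blq_flag = c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, TRUE)
  )
  res <- nca(prof)
  expect_equal(res$cmax, 100)
  # trailing BLQ dropped: last quantifiable point at 24 h anchors AUClast
  direct <- auc_aumc(c(0.25, 0.5, 1, 2, 4, 8, 24),
                     c(0, 20, 80, 100, 60, 30, 5))
  expect_equal(res$auc_last, direct$auc_last)

  allblq <- dplyr::mutate(prof, blq_flag = TRUE)
  expect_error(nca(allblq), "below the quantitation limit")

  # drop_all loses the leading up-slope triangle (0.25-0.5 h, area 2.5)
  res_drop <- nca(prof, blq_policy = "drop_all")
  expect_equal(res_drop$cmax, 100)
  expect_equal(res$auc_last - res_drop$auc_last, 2.5, tolerance = 1e-9)
})

test_that("bioavailability is the dose-normalized AUC ratio", {
  po <- tibble::tibble(dose_mg_per_kg = 5, auc_inf = 2894)
  iv <- tibble::tibble(dose_mg_per_kg = 2, auc_inf = 4857)
  expect_equal(round(bioavailability(po, iv)$f_pct, 2), 23.83)

  same <- tibble::tibble(dose_mg_per_kg = c(2, 2), auc_inf = c(1000, 1000))
  expect_equal(bioavailability(same, same)$f_pct, 100)

  # invariance to joint rescaling of concentrations and of dose units
  sc_po <- dplyr::mutate(po, auc_inf = auc_inf * 1000)
  sc_iv <- dplyr::mutate(iv, auc_inf = auc_inf * 1000)
  expect_equal(bioavailability(sc_po, sc_iv)$f_pct,
               bioavailability(po, iv)$f_pct)
  du_po <- dplyr::mutate(po, dose_mg_per_kg = dose_mg_per_kg * 1000)
  du_iv <- dplyr::mutate(iv, dose_mg_per_kg = dose_mg_per_kg * 1000)
  expect_equal(bioavailability(du_po, du_iv)$f_pct,
               bioavailability(po, iv)$f_pct)

  zero_iv <- tibble::tibble(dose_mg_per_kg = 2, auc_inf = 0)
  expect_error(bioavailability(po, zero_iv), "undefined")

  # per-subject SD scales each oral subject against the IV reference
  po4 <- tibble::tibble(dose_mg_per_kg = 5, auc_inf = c(2800, 2900, 3000, 2870))
  f4 <- bioavailability(po4, iv)
  expect_equal(f4$sd_pct,
               sd(100 * (po4$auc_inf / 5) / (4857 / 2)), tolerance = 1e-12)
})

test_that("group summaries report mean, SD and n per parameter", {
  prof <- simulate_profile(pk_preset("rat_iv", seed = 3, residual_cv = 0))
  res <- nca(prof)
  summ <- summarize_group(res)
  expect_true(all(c("cmax", "cl", "vss", "auc_inf") %in% summ$parameter))
  expect_equal(summ$sd[summ$parameter == "cl"], 0)  # four identical subjects
  expect_equal(summ$n[summ$parameter == "cl"], 4)

  single <- summarize_group(res[1, ])
  expect_true(is.na(single$sd[single$parameter == "cl"]))
})
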