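#' Maximum concentration and its time
#'
#' Reads Cmax and Tmax directly off the observed profile; ties are broken by
#' the earliest time.
#'
#' @param time Sampling times (h), strictly increasing.
#' @param conc Concentrations (ng/mL), same length.
#' @return A one-row tibble with `cmax` and `tmax`.
#' @export
cmax_tmax <- function(time, conc) {
  check_profile_vectors(time, conc)
  if (length(conc) < 1L) abort("Profile has no quantifiable points.")
  i <- which.max(conc)  # which.max returns the first (earliest) maximum
  tibble(cmax = conc[i], tmax = time[i])
}

check_profile_vectors <- function(time, conc) {
  if (length(time) != length(conc)) abort("`time` and `conc` lengths differ.")
  if (any(!is.finite(time)) || any(time < 0)) abort("Times must be finite and >= 0.")
  if (any(diff(time) <= 0)) abort("Times must be strictly increasing.")
  if (any(!is.finite(conc)) || any(conc < 0)) abort("Concentrations must be finite and >= 0.")
  invisible(NULL)
}

#' Terminal slope (lambda_z) selection
#'
#' Estimates the terminal elimination rate constant by ln-linear regression
#' over candidate terminal windows. The default rule considers every window
#' of at least three positive-concentration points that ends at the last
#' quantifiable observation, restricted to times at or after Tmax
#' (strictly after Tmax for oral profiles, where the absorption phase
#' contaminates earlier points), and picks the window with the highest
#' adjusted r-squared among those yielding a positive slope-down.
#'
#' @param time,conc Profile vectors (quantifiable points only).
#' @param route `"iv_bolus"` or `"oral"`; controls whether the Tmax point
#'   itself is eligible.
#' @param min_points Minimum window size (default 3).
#' @return A one-row tibble with `lambda_z` (1/h), `n_lambda_points`,
#'   `adj_r2`, `lambda_z_start_time`.
#' @export
select_lambda_z <- function(time, conc, route = c("iv_bolus", "oral"),
                            min_points = 3) {
  route <- match.arg(route)
  check_profile_vectors(time, conc)
  ct <- cmax_tmax(time, conc)
  eligible <- if (route == "oral") time > ct$tmax else time >= ct$tmax
  eligible <- eligible & conc > 0
  if (route == "oral" && sum(eligible) < min_points) {
    # sparse late-Tmax profile: re-admit the Tmax point rather than abandon
    # the terminal fit outright
    eligible <- time >= ct$tmax & conc > 0
  }
  t_el <- time[eligible]; c_el <- conc[eligible]
  n <- length(t_el)
  if (n < min_points) {
    abort(sprintf(
      "Terminal phase undefined: %d eligible point(s) after Tmax, need >= %d.",
      n, min_points))
  }
  best <- NULL
  for (start in seq_len(n - min_points + 1L)) {
    idx <- start:n
    fit <- lm(log(c_el[idx]) ~ t_el[idx])
    slope <- unname(coef(fit)[2])
    if (!is.finite(slope) || slope >= 0) next
    k <- length(idx)
    r2 <- cor(t_el[idx], log(c_el[idx]))^2
    adj <- 1 - (1 - r2) * (k - 1) / (k - 2)
    if (is.null(best) || adj > best$adj_r2 + 1e-12) {
      best <- tibble(
        lambda_z = -slope,
        n_lambda_points = k,
        adj_r2 = adj,
        lambda_z_start_time = t_el[start]
      )
    }
  }
  if (is.null(best)) {
    abort("Terminal phase undefined: no candidate window gives a positive lambda_z.")
  }
  best
}

#' Trapezoidal AUC and AUMC to the last observation
#'
#' Interval-wise trapezoids for the area under the concentration-time curve
#' and under the first-moment curve. `"linear_up_log_down"` (the default used
#' in standard NCA practice) applies the logarithmic trapezoid on strictly
#' decreasing intervals with both endpoints positive and the linear trapezoid
#' elsewhere; `"linear"` uses linear trapezoids throughout.
#'
#' @param time,conc Profile vectors (>= 2 points).
#' @param method `"linear_up_log_down"` or `"linear"`.
#' @return A one-row tibble with `auc_last` (ng·h/mL) and `aumc_last`
#'   (ng·h²/mL).
#' @export
#' @examples
#' auc_aumc(c(0, 1), c(100, 50), method = "linear")           # auc 75
#' auc_aumc(c(0, 1), c(100, 50), method = "linear_up_log_down")  # auc 50/log(2)
auc_aumc <- function(time, conc, method = c("linear_up_log_down", "linear")) {
  method <- match.arg(method)
  check_profile_vectors(time, conc)
  if (length(time) < 2L) abort("AUC needs at least two quantifiable points.")
  auc <- 0; aumc <- 0
  for (i in seq_len(length(time) - 1L)) {
    t1 <- time[i]; t2 <- time[i + 1L]
    c1 <- conc[i]; c2 <- conc[i + 1L]
    dt <- t2 - t1
    log_down <- method == "linear_up_log_down" && c2 < c1 && c2 > 0
    if (log_down) {
      k <- log(c1 / c2) / dt
      auc <- auc + (c1 - c2) / k
      aumc <- aumc + (t1 * c1 - t2 * c2) / k + (c1 - c2) / k^2
    } else {
      auc <- auc + dt * (c1 + c2) / 2
      aumc <- aumc + dt * (t1 * c1 + t2 * c2) / 2
    }
  }
  tibble(auc_last = auc, aumc_last = aumc)
}

#' Extrapolate AUC and AUMC to infinity
#'
#' `auc_inf = auc_last + clast/lambda_z` and
#' `aumc_inf = aumc_last + clast*tlast/lambda_z + clast/lambda_z^2`, with the
#' extrapolated percentage `100*(auc_inf - auc_last)/auc_inf`. A warning is
#' issued when more than 20% of the total area is extrapolated, the usual
#' reliability threshold.
#'
#' @param auc_last,aumc_last Areas to the last quantifiable point.
#' @param clast Last quantifiable concentration (ng/mL), > 0.
#' @param tlast Time of `clast` (h).
#' @param lambda_z Terminal rate constant (1/h), > 0.
#' @return A one-row tibble with `auc_inf`, `aumc_inf`, `pct_extrapolated`.
#' @export
extrapolate <- function(auc_last, aumc_last, clast, tlast, lambda_z) {
  assert_number(lambda_z, "lambda_z", lower = 0, strict_lower = TRUE)
  assert_number(clast, "clast", lower = 0)
  auc_inf <- auc_last + clast / lambda_z
  aumc_inf <- aumc_last + clast * tlast / lambda_z + clast / lambda_z^2
  pct <- 100 * (auc_inf - auc_last) / auc_inf
  if (pct > 20) {
    warn(sprintf("%.1f%% of AUCinf is extrapolated (> 20%%); terminal estimate may be unreliable.", pct))
  }
  tibble(auc_inf = auc_inf, aumc_inf = aumc_inf, pct_extrapolated = pct)
}

#' Clearance, MRT, Vss and terminal half-life after IV bolus
#'
#' Standard noncompartmental identities: `CL = dose/AUCinf`,
#' `MRT = AUMCinf/AUCinf`, `Vss = CL * MRT`, `t_half = ln(2)/lambda_z`.
#' With dose in mg/kg and AUC in ng·h/mL, the dose is converted to ng/kg
#' (x 1e6) so clearance comes out in mL/h/kg and Vss in mL/kg.
#'
#' @param dose Dose (mg/kg), > 0.
#' @param auc_inf AUC extrapolated to infinity (ng·h/mL), > 0.
#' @param aumc_inf AUMC extrapolated to infinity (ng·h²/mL).
#' @param lambda_z Terminal rate constant (1/h), > 0.
#' @return A one-row tibble with `cl` (mL/h/kg), `mrt` (h), `vss` (mL/kg),
#'   `t_half` (h).
#' @export
#' @examples
#' derive_iv_parameters(dose = 2, auc_inf = 4857,
#'                      aumc_inf = 4857 * 10, lambda_z = 0.05)
derive_iv_parameters <- function(dose, auc_inf, aumc_inf, lambda_z) {
  assert_number(dose, "dose", lower = 0, strict_lower = TRUE)
  assert_number(auc_inf, "auc_inf", lower = 0, strict_lower = TRUE)
  assert_number(lambda_z, "lambda_z", lower = 0, strict_lower = TRUE)
  cl <- dose * 1e6 / auc_inf
  mrt <- aumc_inf / auc_inf
  tibble(cl = cl, mrt = mrt, vss = cl * mrt, t_half = log(2) / lambda_z)
}

# apply the BLQ policy to a per-subject profile; returns the analysable
# time/conc vectors
apply_blq_policy <- function(time, conc, blq,
                             policy = c("zero_pre_tmax_drop_post",
                                        "drop_all", "zero_all")) {
  policy <- match.arg(policy)
  if (all(blq)) abort("Profile is entirely below the quantitation limit.")
  if (policy == "drop_all") {
    return(list(time = time[!blq], conc = conc[!blq]))
  }
  if (policy == "zero_all") {
    conc[blq] <- 0
    return(list(time = time, conc = conc))
  }
  tmax <- time[!blq][which.max(conc[!blq])]
  keep <- !blq | time < tmax
  conc[blq & time < tmax] <- 0
  list(time = time[keep], conc = conc[keep])
}

#' Noncompartmental analysis of concentration-time profiles
#'
#' Runs the full NCA per subject: BLQ policy, Cmax/Tmax, trapezoidal
#' AUC/AUMC to the last quantifiable point, terminal-slope selection,
#' extrapolation to infinity, terminal half-life and MRT, and -- for IV bolus
#' profiles -- clearance and steady-state volume of distribution. No
#' back-extrapolation to time zero is performed: the observed profile starts
#' at the first sampling time.
#'
#' @param profiles A data frame with columns `subject`, `route`,
#'   `dose_mg_per_kg`, `time_h`, `conc_ng_per_ml`, and optionally `blq_flag`
#'   (absent flags are derived from `lloq` when given, else all observations
#'   are treated as quantifiable).
#' @param method AUC method, `"linear_up_log_down"` (default) or `"linear"`.
#' @param blq_policy How to treat flagged observations:
#'   `"zero_pre_tmax_drop_post"` (default: pre-Tmax BLQ set to zero, post-Tmax
#'   BLQ excluded), `"drop_all"`, or `"zero_all"`.
#' @param lloq Optional LLOQ (ng/mL) used to derive missing BLQ flags.
#' @param min_lambda_points Minimum terminal-window size (default 3).
#'
#' @return A tibble of class `nca_result`, one row per subject, with columns
#'   `subject`, `route`, `dose_mg_per_kg`, `cmax`, `tmax`, `lambda_z`,
#'   `t_half`, `auc_last`, `auc_inf`, `aumc_last`, `aumc_inf`, `mrt`, `cl`,
#'   `vss`, `pct_extrapolated`, `n_lambda_points`, `adj_r2`, `method`.
#'   `cl` and `vss` are `NA` for oral profiles (they would be CL/F, V/F).
#' @seealso [bioavailability()], [summarize_group()]
#' @export
#' @examples
#' prof <- simulate_profile(pk_preset("rat_iv", seed = 3, residual_cv = 0))
#' nca(prof)
nca <- function(profiles,
                method = c("linear_up_log_down", "linear"),
                blq_policy = c("zero_pre_tmax_drop_post", "drop_all", "zero_all"),
                lloq = NULL,
                min_lambda_points = 3) {
  method <- match.arg(method)
  blq_policy <- match.arg(blq_policy)
  assert_columns(profiles,
                 c("subject", "route", "dose_mg_per_kg", "time_h", "conc_ng_per_ml"),
                 "profile table")
  if (!"blq_flag" %in% names(profiles)) {
    profiles$blq_flag <- if (is.null(lloq)) FALSE
                         else profiles$conc_ng_per_ml < lloq
  }

  out <- profiles |>
    dplyr::group_by(.data$subject, .data$route, .data$dose_mg_per_kg) |>
    dplyr::group_modify(function(d, key) {
      d <- dplyr::arrange(d, .data$time_h)
      pr <- apply_blq_policy(d$time_h, d$conc_ng_per_ml, d$blq_flag, blq_policy)
      nca_single(pr$time, pr$conc, key$route, key$dose_mg_per_kg,
                 method, min_lambda_points)
    }) |>
    dplyr::ungroup()
  class(out) <- c("nca_result", class(out))
  out
}

nca_single <- function(time, conc, route, dose, method, min_lambda_points) {
  ct <- cmax_tmax(time, conc)
  quant <- conc > 0
  tq <- time[quant]; cq <- conc[quant]
  if (length(tq) < 2L) abort("Fewer than two quantifiable points; NCA undefined.")
  # leading zero (oral pre-dose) participates in the up-slope trapezoid
  first_q <- which(quant)[1]
  if (first_q > 1L) {
    tq <- c(time[first_q - 1L], tq)
    cq <- c(0, cq)
  }
  areas <- auc_aumc(tq, cq, method = method)
  lam <- select_lambda_z(time[quant], conc[quant], route = route,
                         min_points = min_lambda_points)
  tlast <- tq[length(tq)]; clast <- cq[length(cq)]
  ext <- extrapolate(areas$auc_last, areas$aumc_last, clast, tlast, lam$lambda_z)
  mrt <- ext$aumc_inf / ext$auc_inf
  if (route == "iv_bolus") {
    iv <- derive_iv_parameters(dose, ext$auc_inf, ext$aumc_inf, lam$lambda_z)
    cl <- iv$cl; vss <- iv$vss
  } else {
    cl <- NA_real_; vss <- NA_real_
  }
  tibble(
    cmax = ct$cmax, tmax = ct$tmax,
    lambda_z = lam$lambda_z, t_half = log(2) / lam$lambda_z,
    auc_last = areas$auc_last, auc_inf = ext$auc_inf,
    aumc_last = areas$aumc_last, aumc_inf = ext$aumc_inf,
    mrt = mrt, cl = cl, vss = vss,
    pct_extrapolated = ext$pct_extrapolated,
    n_lambda_points = lam$n_lambda_points, adj_r2 = lam$adj_r2,
    method = method
  )
}

#' Dose-normalized absolute bioavailability
#'
#' `F = 100 * mean(AUC_po/dose_po) / mean(AUC_iv/dose_iv)`: the ratio of
#' dose-normalized mean areas (default), with the SD obtained by scaling each
#' oral subject's dose-normalized AUC against the mean IV reference. A
#' per-subject-ratio mode (`method = "per_subject"`, mean of individual
#' ratios against the IV mean) is also available.
#'
#' @param po,iv NCA results (or any data frames) carrying `dose_mg_per_kg`
#'   and the AUC column named by `basis` for the oral and IV arms.
#' @param basis `"auc_inf"` (default) or `"auc_last"`.
#' @param method `"ratio_of_means"` (default) or `"per_subject"`.
#' @return A one-row tibble with `f_pct`, `sd_pct`, `n_po`, `n_iv`, `basis`.
#' @export
#' @examples
#' po <- tibble::tibble(dose_mg_per_kg = 5, auc_inf = 2894)
#' iv <- tibble::tibble(dose_mg_per_kg = 2, auc_inf = 4857)
#' bioavailability(po, iv)  # 23.83%
bioavailability <- function(po, iv, basis = c("auc_inf", "auc_last"),
                            method = c("ratio_of_means", "per_subject")) {
  basis <- match.arg(basis)
  method <- match.arg(method)
  for (arm in list(po, iv)) {
    assert_columns(arm, c("dose_mg_per_kg", basis), "NCA result table")
  }
  if (nrow(po) < 1L || nrow(iv) < 1L) abort("Each arm needs at least one profile.")
  if (any(po$dose_mg_per_kg <= 0) || any(iv$dose_mg_per_kg <= 0)) {
    abort("Doses must be > 0.")
  }
  po_dn <- po[[basis]] / po$dose_mg_per_kg
  iv_dn <- iv[[basis]] / iv$dose_mg_per_kg
  iv_ref <- mean(iv_dn)
  if (iv_ref <= 0) abort("Mean IV dose-normalized AUC is zero; F undefined.")
  per_subject_f <- 100 * po_dn / iv_ref
  f <- if (method == "ratio_of_means") 100 * mean(po_dn) / iv_ref
       else mean(per_subject_f)
  tibble(
    f_pct = f,
    sd_pct = if (length(per_subject_f) >= 2) sd(per_subject_f) else NA_real_,
    n_po = nrow(po), n_iv = nrow(iv),
    basis = basis
  )
}

#' Group summary of NCA parameters
#'
#' Arithmetic mean and sample SD of each numeric NCA parameter across
#' subjects, one row per parameter in the conventional reporting layout.
#'
#' @param results An `nca_result` tibble (one row per subject).
#' @return A tibble with `parameter`, `mean`, `sd`, `n`. `sd` is `NA` for a
#'   single subject.
#' @export
summarize_group <- function(results) {
  if (nrow(results) < 1L) abort("`results` must contain at least one subject.")
  params <- c("cmax", "tmax", "t_half", "lambda_z", "auc_last", "auc_inf",
              "aumc_last", "aumc_inf", "mrt", "cl", "vss", "pct_extrapolated")
  params <- intersect(params, names(results))
  results |>
    dplyr::select(dplyr::all_of(params)) |>
    tidyr::pivot_longer(dplyr::everything(),
                        names_to = "parameter", values_to = "value") |>
    dplyr::group_by(.data$parameter) |>
    dplyr::summarise(
      mean = mean(.data$value, na.rm = TRUE),
      sd = if (sum(!is.na(.data$value)) >= 2) sd(.data$value, na.rm = TRUE) else NA_real_,
      n = sum(!is.na(.data$value)),
      .groups = "drop"
    ) |>
    dplyr::arrange(match(.data$parameter, params))
}
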