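# Independent oracles kept deliberately separate from the package internals.

# Weighted least squares by direct solution of the normal equations.
wls_normal_equations <- function(x, y, w) {
  X <- cbind(1, x)
  XtWX <- t(X) %*% (w * X)
  XtWy <- t(X) %*% (w * y)
  beta <- solve(XtWX, XtWy)
  c(intercept = beta[1], slope = beta[2])
}

# Analytic AUC of C(t) = c0 * exp(-k t) over [0, T].
analytic_auc_monoexp <- function(c0, k, T) c0 / k * (1 - exp(-k * T))

# Analytic AUMC of the same curve over [0, T].
analytic_aumc_monoexp <- function(c0, k, T) {
  c0 / k^2 - exp(-k * T) * (c0 * T / k + c0 / k^2)
}

# Build a chromatogram object from explicit values, bypassing the simulator,
# so boundary S/N cases can be pinned exactly.
manual_chromatogram <- function(time, intensity, apex_time, window) {
  structure(
    list(
      trace = tibble::tibble(time_min = time, intensity = intensity),
      peak_apex_time = apex_time,
      baseline_window = window
    ),
    class = "chromatogram"
  )
}

# Two replicate values with a prescribed sample mean and SD.
pair_with_mean_sd <- function(m, s) c(m - s / sqrt(2), m + s / sqrt(2))

# Standard rat-like one-compartment truth used across NCA tests.
rat_truth <- list(dose = 2, V = 5775, CL = 413.6)
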