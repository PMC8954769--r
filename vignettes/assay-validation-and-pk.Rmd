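---
title: "Methods: weighted calibration, validation statistics, stability kinetics, and NCA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: weighted calibration, validation statistics, stability kinetics, and NCA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(assaypk)
```

# What this package computes

`assaypk` implements the complete computational chain behind a quantitative
LC-MS/MS bioanalytical assay and its pharmacokinetic application, using the
assay developed for the PROTAC degrader ARV-110 in rat and mouse plasma as
its reference scenario. The chain is:

1. **Calibration** — a 1/x²-weighted linear fit of analyte:internal-standard
   (IS) peak-area ratio against nominal concentration over 2–3000 ng/mL,
   back-calculation, and guideline calibrator acceptance.
2. **Validation statistics** — accuracy (%RE), precision (CV%), the
   Matuszewski three-set partition of matrix effect, extraction recovery and
   process efficiency (with IS normalization), stability percentages, and
   the LLOQ signal-to-noise check.
3. **Stability kinetics** — first-order elimination constants and
   half-lives from %-remaining time courses (plasma and hepatic microsomes).
4. **Noncompartmental analysis (NCA)** — Cmax/Tmax, terminal slope,
   trapezoidal AUC/AUMC, extrapolation to infinity, CL, MRT, Vss, and
   dose-normalized absolute bioavailability.
5. **Synthetic data** — every input above can be generated with known
   ground truth, which is what the test suite exercises.

Because the raw instrument and animal data behind the reference assay were
never deposited, the package is organised around *recovery testing*: the
generator module produces data whose truth is known exactly, and every
analysis stage is required to return that truth (exactly in the noise-free
limit, within quantified tolerances under noise).

# The calibration model

The response model is a straight line through the area ratio,
$y = a + b\,x$, fitted by weighted least squares minimising
$\sum_i w_i (y_i - a - b x_i)^2$ with $w_i = 1/x_i^2$ by default. The 1/x²
weighting reflects the proportional (constant-CV) error of LC-MS/MS peak
areas: unweighted fits let the 2000–3000 ng/mL standards dominate and bias
the low end, where the LLOQ sits. The test suite demonstrates this directly
(mean back-calculated bias at the 2 ng/mL LLOQ under 1/x² weighting is no
worse than unweighted, over 200 simulated curves at 5% CV).

**The correlation coefficient under weighting.** Assay reports quote a
single `r` per curve without defining it for a weighted fit. We use the
weighted Pearson correlation with the same 1/x² weights as the regression:
$r = \mathrm{cov}_w(x,y)/\sqrt{\mathrm{var}_w(x)\,\mathrm{var}_w(y)}$.
It is invariant to rescaling of the response axis and equals 1 exactly on
noise-free data. Linearity passes at $r \ge 0.990$ (inclusive).

**Calibrator acceptance and re-fit.** Back-calculated standards must lie
within ±20% of nominal at the LLOQ and ±15% elsewhere, with ≥75% of
calibrators passing. When `auto_refit = TRUE`, one failing calibrator that
is not at the LLOQ or ULOQ level may be dropped and the curve refit once —
common guideline practice; the dropped point is recorded in the returned
object. Zero/blank calibrators are never part of the regression.

**Precision of reported coefficients.** Report rendering uses 4 significant
figures (round-half-even, via `signif()`); full precision is retained
internally and in the full-precision CSV outputs.

# Validation statistics

- **%RE** is $100\,|\bar{c} - c_{nom}|/c_{nom}$, reported as an absolute
  percentage (the convention of published validation tables); the signed
  value is kept in a secondary column of `qc_summary()`.
- **CV%** is $100\,s/\bar{c}$ with the sample (n−1) SD, computed on
  back-calculated concentrations. (Computing it on raw area ratios gives a
  different number because back-calculation is affine with a non-zero
  intercept; the concentration basis matches how validation tables are
  tabulated, e.g. SD 249.6 at mean 2513 gives 9.932%.)
- **Matuszewski sets.** Set 1 is the neat solution, set 2 the blank-matrix
  extract spiked *after* extraction, set 3 the matrix spiked *before*
  extraction. Matrix effect = 100·mean(set2)/mean(set1); recovery =
  100·mean(set3)/mean(set2); process efficiency = 100·mean(set3)/mean(set1).
  Computed from the same set means, $PE = ME \times Rec / 100$ holds to
  machine precision — the package treats this identity as a contract and the
  tests enforce it. (Published tables sometimes violate the identity
  slightly, implying per-replicate pairings that cannot be reconstructed
  from summary data; we document the identity-exact convention instead of
  reverse-engineering one.) The SD/CV of each metric is taken over the
  per-replicate numerator areas divided by the denominator-set *mean*, so
  the spread reflects the numerator set, matching the "CV of the matrix
  effect" convention.
- **IS normalization** divides an analyte metric by the IS metric
  (×100), cancelling suppression shared between analyte and IS.
- **Stability** is 100·mean(measured)/reference with the reference taken as
  the nominal concentration by default (consistent with published stability
  percentages); a freshly-prepared-reference mode is available through the
  `reference` argument of `stability_summary()`.
- **Signal-to-noise** is (apex − baseline mean)/baseline SD over a declared
  peak-free baseline window; LLOQ eligibility requires S/N strictly
  greater than 10. A zero-variance baseline is reported as infinite with a
  warning; a flat trace reports 0.

# Stability kinetics

The elimination rate constant is the negated slope of the ordinary
least-squares regression of $\ln(\%\,\text{remaining})$ on incubation time,
and $T_{1/2} = \ln 2 / k_e$. Natural logarithms are used so the slope *is*
the rate constant; the half-life relation $T_{1/2} = \ln 2/k_e$ fixes this
convention (a base-10 fit would need a ln 10 conversion and buys nothing).
The $t = 0$ sample is a measured point and enters the regression like any
other. Replicates are pooled into one regression by default (`fit_ke()`);
per-replicate fits (`fit_ke_each()`) are available since published
mean ± SD triplicates could come from either convention. A non-decaying
series (slope ≥ 0, as seen in stable microsomal incubations) returns
`ke ≤ 0` with the half-life as an `NA` sentinel, not an error. A constant
series is snapped to slope exactly 0 so the sentinel triggers
deterministically.

# Noncompartmental analysis

All computation happens in one canonical unit system: time h, concentration
ng/mL, dose mg/kg. With dose converted to ng/kg (×10⁶), CL = dose/AUCinf
comes out in mL/h/kg and Vss = CL·MRT in mL/kg.

- **Cmax/Tmax** are read directly off the profile; ties go to the earliest
  time.
- **AUC/AUMC** use interval-wise trapezoids. The default
  `linear_up_log_down` method applies the logarithmic trapezoid
  $\Delta AUC = (c_1 - c_2)/k$ with $k = \ln(c_1/c_2)/\Delta t$ on strictly
  decreasing intervals with positive endpoints (exact on monoexponential
  decline) and the linear trapezoid elsewhere; AUMC uses the matching
  moment formulas. On any strictly decreasing profile the log-down area is
  ≤ the linear area.
- **λz selection**: among all windows of ≥3 terminal points ending at the
  last quantifiable observation, the window maximising the adjusted r² of
  the ln-linear fit wins; λz must be positive. The Tmax point is excluded
  from candidate windows for oral profiles (absorption contaminates it).
  One pragmatic extension: when noise pushes an oral subject's observed
  Tmax so late that fewer than three strictly-later points remain — which
  a 9-point sparse schedule does produce at 10% residual error — the Tmax
  point is re-admitted rather than abandoning the subject. Ties in adjusted
  r² go to the longer window.
- **Extrapolation**: AUCinf = AUClast + Clast/λz, with the matching AUMC
  tail; a warning is raised when more than 20% of AUCinf is extrapolated.
- **No C0 back-extrapolation**: the analysed profile starts at the first
  observed sample (0.083 h in the rat IV design), consistent with reporting
  Tmax at the first sampling time for IV bolus data. On such sparse
  schedules this leaves a small negative bias in AUC (and hence a small
  positive bias in CL) that vanishes with denser sampling — the test suite
  demonstrates the monotone error decay.
- **BLQ policy** (default `zero_pre_tmax_drop_post`): flagged observations
  before Tmax are set to 0 (they lie on the rising limb where zero is the
  natural lower bound), flagged observations after Tmax are excluded
  (substituting 0 or LLOQ/2 would distort the terminal fit). `drop_all` and
  `zero_all` are available for sensitivity analysis.
- **Bioavailability**: $F = 100 \cdot \overline{AUC_{po}/D_{po}} \,/\,
  \overline{AUC_{iv}/D_{iv}}$ on the AUCinf basis by default — the ratio of
  dose-normalized means, which reproduces published group-level F values
  from group-mean AUCs exactly. Its SD scales each oral subject's
  dose-normalized AUC against the mean IV reference. A per-subject-ratio
  mode exists but is not the default. The AUC basis (`auc_inf` vs
  `auc_last`) is a recorded, user-visible setting.

# The synthetic-data generator

The generator emulates the study conditions of the reference assay:

- **Calibration/QC responses**: the true line slope 0.001310 per (ng/mL),
  intercept 0.000042, over levels 2, 3, 10, 100, 1000, 2000, 3000 ng/mL;
  proportional Normal noise with CV 6% by default (the mid-single-digit CVs
  of typical validated runs). QC levels 2/5/100/2500 ng/mL with 6
  replicates.
- **Matuszewski sets**: ~75% ionization suppression with ~100% extraction
  recovery by default (the magnitudes of a protein-precipitation assay with
  visible suppression), 5 replicates per set; separate truths available for
  the IS.
- **Decay series**: the 7-point schedule 0, 15, 30, 60, 120, 360, 480 min;
  half-life presets spanning tens of minutes (plasma at 37 °C: 44/93/24 min
  for rat/mouse/human) to many hours (microsomes: 2215/415/986 min).
- **Concentration–time profiles**: closed-form one- and two-compartment
  solutions (IV bolus and first-order oral absorption into the central
  compartment; the Bateman equation in the one-compartment oral case).
  The `pk_preset()` scenarios carry the rat/mouse magnitudes —
  CL 413.6/180.9 mL/h/kg, Vss 5775/2366 mL/kg, IV 2 mg/kg, PO 5 mg/kg,
  F 23.83/37.89%, with the corresponding sparse sampling schedules and
  cohorts of 4 — and are labelled presets, not fits. Oral `ka`
  (0.37/0.44 h⁻¹) is chosen so the simulated Tmax lands near the observed
  4.8–5.5 h.
- **Residual error** on profiles is multiplicative lognormal,
  $C_{obs} = C \cdot e^{\eta}$, $\eta \sim N(0, \sigma)$ with
  $\sigma = \sqrt{\ln(1 + cv^2)}$ so the CV equals the nominal value and
  concentrations stay positive; the default 10% is a typical bioanalytical
  run-to-run magnitude. Between-subject lognormal variability on CL and V
  is exposed (`bsv_cv_cl`, `bsv_cv_v`) but defaults to 0, as no data
  constrain it.
- **BLQ values are emitted and flagged**, never censored, so NCA BLQ
  policies are testable.
- **Chromatograms**: a Gaussian peak plus white baseline noise on a regular
  grid, with a constant baseline offset of 5 noise-SDs keeping intensities
  non-negative without clipping bias (S/N subtracts the baseline mean, so
  the offset cancels).

What the generator does **not** emulate — and what passing tests therefore
do not show about real data: drift and carry-over between injections,
heavy-tailed or autocorrelated instrument noise, the secondary absorption
peak at 4–8 h seen in mouse IV profiles (enteric recirculation is out of
scope), matrix lot-to-lot variability, and any misspecification between the
assumed compartmental model and real disposition. Recovery results certify
the *arithmetic* of the chain, not the biology.

# Numerical and degenerate-input choices

- Every stochastic generator requires an explicit integer seed; identical
  seed + configuration gives bit-identical output.
- Calibration with a single distinct level, weighted fits with zero
  concentrations, CVs of fewer than 2 replicates, logs of non-positive
  percentages, ka = ke in the Bateman form, all-BLQ profiles, and empty
  baseline windows are rejected with specific errors rather than returning
  NaN.
- ka ≤ ke (flip-flop absorption) must be requested explicitly
  (`allow_flip_flop = TRUE`).
- Report rounding (4 significant figures) is confined to the presentation
  layer (`write_report(digits =)` and print methods); all computation and
  the full-precision CSVs keep double precision, and numeric columns
  round-trip through CSV to at least 12 significant digits.
- The pipeline manifest records seeds, method flags, noise levels and the
  package version; identical configurations produce byte-identical output
  files.

# Problem sizes used by the test and acceptance suites

Chosen to make Monte-Carlo tolerances meaningful while staying quick:
CV-convergence checks use 10⁴ replicates (3 Monte-Carlo SEs); the
weighting-bias comparison uses 200 curves; calibrator failure-rate
monotonicity uses 500 seeds; half-life recovery uses 100 noise-free and
500 noisy series; NCA dense-sampling recovery uses ~160 log-spaced points
out to 14 terminal half-lives (within 0.5% of truth); group-level
bioavailability is recovered from 4-subject cohorts at 10% residual error.

# Interface choices

This is an analysis package used from R: the exported functions
(`simulate_* → fit_calibration → qc_summary / matuszewski_summary →
kinetics_summary → nca → bioavailability`), the `run_pipeline()`
orchestrator with its YAML configuration, and `scripts/acceptance.R`
constitute the pipeline surface; no separate shell tool is shipped. Out of
scope by design: quadratic/4PL calibration, dilution integrity and
incurred-sample reanalysis, Michaelis–Menten/CLint scaling, compartmental
model *fitting*, urine or partial-area analyses, and vendor raw-file
formats.
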