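#' DCE-MRI relaxometry and pharmacokinetic models
#'
#' Variable flip angle (VFA) T1 mapping from spoiled gradient-recalled (SPGR)
#' acquisitions, conversion of dynamic SPGR signal to longitudinal relaxation
#' rate R1(t) and contrast agent concentration, the standard Tofts model, and
#' the shutter-speed fast exchange regime (FXR) model in which the observable
#' R1 is the smaller eigenvalue of the two-site (intracellular/extracellular)
#' water exchange relaxation matrix.
#'
#' Internally all times are seconds and all rates s^-1; Ktrans and kep cross
#' the API in min^-1 (the unit in which they are conventionally reported).
#'
#' @name dce_relaxometry
NULL

# Acquisition defaults of the emulated protocol.
QMRI_TR_MS <- 7           # dynamic + VFA repetition time, ms
QMRI_FA_DYN <- 15         # dynamic flip angle, degrees
QMRI_VFA_ANGLES <- c(30, 15, 5)
QMRI_R1_RELAXIVITY <- 4.0 # contrast agent longitudinal relaxivity, mM^-1 s^-1
QMRI_BLOOD_T10 <- 1.65    # blood T10 at 3T, s (literature default)
QMRI_HEMATOCRIT <- 0.45

#' Steady-state SPGR signal
#'
#' \eqn{S = M_0 \sin\alpha (1 - E_1) / (1 - E_1 \cos\alpha)} with
#' \eqn{E_1 = e^{-TR \cdot R_1}}.
#'
#' @param R1 longitudinal relaxation rate (s^-1), vectorized.
#' @param M0 equilibrium signal scale.
#' @param alpha flip angle, degrees, in (0, 90).
#' @param TR repetition time, ms.
#' @export
spgr_signal <- function(R1, M0, alpha, TR = QMRI_TR_MS) {
  assert_that(all(R1 > 0), "R1 must be positive")
  assert_that(is_number(alpha) && alpha > 0 && alpha < 90,
              "alpha must lie in (0, 90) degrees")
  assert_that(is_number(TR) && TR > 0, "TR must be positive (ms)")
  a <- deg2rad(alpha)
  E1 <- exp(-TR / 1000 * R1)
  M0 * sin(a) * (1 - E1) / (1 - E1 * cos(a))
}

#' Fit precontrast T1 from a variable flip angle series
#'
#' Linearization (S/sin(a) vs S/tan(a), slope = E1) provides the initial
#' estimate, refined by box-constrained nonlinear least squares on the raw
#' signal. Noiseless SPGR input is recovered exactly by the linear step.
#'
#' @param signals per-angle steady-state magnitudes.
#' @param flip_angles degrees, distinct, length >= 2.
#' @param TR ms.
#' @return list with `T10` (s), `M0`, `rss`, `converged`.
#' @export
fit_t10_vfa <- function(signals, flip_angles = QMRI_VFA_ANGLES,
                        TR = QMRI_TR_MS) {
  assert_that(length(signals) == length(flip_angles),
              "signals and flip_angles must have equal length")
  assert_that(length(unique(flip_angles)) >= 2, "need >= 2 distinct angles")
  assert_that(all(signals >= 0), "signals must be non-negative")
  if (all(signals == 0)) stop_qmri("all-zero VFA signals")
  a <- deg2rad(flip_angles)
  y <- signals / sin(a)
  x <- signals / tan(a)
  co <- stats::coef(stats::lm(y ~ x))
  E1 <- unname(co[2])
  if (!is.finite(E1) || E1 <= 0 || E1 >= 1) {
    return(list(T10 = NA_real_, M0 = NA_real_, rss = NA_real_,
                converged = FALSE))
  }
  T10 <- -(TR / 1000) / log(E1)
  M0 <- unname(co[1]) / (1 - E1)

  lower <- c(1e-3, 1e-9)
  upper <- c(20, 100 * max(signals))
  resid_fn <- function(p) {
    e <- exp(-TR / 1000 / p[1])
    signals - p[2] * sin(a) * (1 - e) / (1 - e * cos(a))
  }
  o <- .lm_box(pmin(pmax(c(T10, M0), lower), upper), resid_fn, lower, upper)
  list(T10 = o$par[1], M0 = o$par[2], rss = o$rss, converged = o$converged)
}

#' Convert a dynamic SPGR signal series to R1(t)
#'
#' The equilibrium scale M0 is calibrated from the mean of the precontrast
#' baseline phases together with the supplied R10; each phase's E1 is then
#' solved algebraically from the SPGR equation and R1 = -ln(E1)/TR.
#'
#' @param signals dynamic tissue signal per phase.
#' @param n_baseline number of precontrast phases (>= 1).
#' @param R10 precontrast relaxation rate (s^-1), e.g. from [fit_t10_vfa()].
#' @param alpha flip angle, degrees.
#' @param TR ms.
#' @return list: `R1` (s^-1 per phase, `NA` where the signal is outside the
#'   SPGR range), `valid` logical flags, `M0`.
#' @export
dynamic_signal_to_R1 <- function(signals, n_baseline, R10,
                                 alpha = QMRI_FA_DYN, TR = QMRI_TR_MS) {
  assert_that(is_number(R10) && R10 > 0, "R10 must be positive")
  assert_that(n_baseline >= 1 && n_baseline < length(signals),
              "n_baseline must be in [1, n_phases)")
  a <- deg2rad(alpha)
  TRs <- TR / 1000
  E10 <- exp(-TRs * R10)
  s_base <- mean(signals[seq_len(n_baseline)])
  M0 <- s_base * (1 - E10 * cos(a)) / (sin(a) * (1 - E10))

  # S = M0 sin a (1-E1)/(1-E1 cos a)  =>  E1 = (M0 sin a - S)/(M0 sin a - S cos a)
  E1 <- (M0 * sin(a) - signals) / (M0 * sin(a) - signals * cos(a))
  valid <- is.finite(E1) & E1 > 0 & E1 < 1
  R1 <- rep(NA_real_, length(signals))
  R1[valid] <- -log(E1[valid]) / TRs
  if (any(!valid)) {
    qmri_log("signal_to_R1", "%d phase(s) outside the SPGR signal range",
             sum(!valid))
  }
  list(R1 = R1, valid = valid, M0 = M0)
}

#' Contrast agent concentration from R1
#'
#' Linear fast-exchange-limit relation `Ct = (R1t - R10) / r1`; small
#' negative excursions (noise) are clipped to zero and flagged.
#'
#' @param R1t R1 time course (s^-1).
#' @param R10 precontrast rate (s^-1).
#' @param r1 relaxivity (mM^-1 s^-1).
#' @return list: `Ct` (mM), `clipped` logical flags.
#' @export
concentration_from_R1 <- function(R1t, R10, r1 = QMRI_R1_RELAXIVITY) {
  assert_that(is_number(r1) && r1 > 0, "r1 must be positive")
  Ct <- (R1t - R10) / r1
  clipped <- !is.na(Ct) & Ct < 0
  Ct[clipped] <- 0
  list(Ct = Ct, clipped = clipped)
}

# Causal convolution Ct(t) = Ktrans_s * int_0^t Cp(u) exp(-kep_s (t-u)) du.
# Cp is treated as piecewise linear between its samples and the convolution
# of each linear segment with the exponential kernel is evaluated in closed
# form, so the quadrature is exact for the AIF actually supplied; accuracy
# against a continuous AIF is set only by the AIF sampling density. The
# integration grid is the union of the AIF grid and the output grid.
.tofts_conv <- function(times, aif_times, aif_cp, Ktrans_min, kep_min) {
  kt <- Ktrans_min / 60
  k <- kep_min / 60
  grid <- sort(unique(c(times, aif_times[aif_times >= times[1] &
                                           aif_times <= times[length(times)]])))
  cp <- stats::approx(aif_times, aif_cp, xout = grid, rule = 2)$y
  n <- length(grid)
  acc <- numeric(n)
  for (i in 2:n) {
    dt <- grid[i] - grid[i - 1]
    E <- exp(-k * dt)
    if (k * dt > 1e-8) {
      A <- (1 - E) / k              # int e^{-k(dt-v)} dv
      B <- (dt - A) / k             # int v e^{-k(dt-v)} dv
    } else {
      A <- dt
      B <- dt^2 / 2
    }
    slope <- (cp[i] - cp[i - 1]) / dt
    acc[i] <- acc[i - 1] * E + cp[i - 1] * A + slope * B
  }
  kt * acc[match(times, grid)]
}

#' Tofts model tissue concentration
#'
#' \eqn{C_t(t) = K^{trans} \int_0^t C_p(u) e^{-k_{ep}(t-u)} du} with
#' \eqn{k_{ep} = K^{trans}/v_e}. The arterial input is treated as piecewise
#' linear between its samples and each linear segment is convolved with the
#' exponential kernel in closed form (exact for the supplied samples).
#'
#' @param times seconds, strictly increasing from 0 (or the first sample).
#' @param Ktrans volume transfer constant, min^-1, `>= 0`.
#' @param ve extravascular-extracellular volume fraction in (0, 1].
#' @param aif list with `times` (s) and `Cp` (mM) as from [population_aif()];
#'   sample the AIF densely when high absolute accuracy is needed.
#' @return tissue concentration (mM) at `times`.
#' @export
tofts_concentration <- function(times, Ktrans, ve, aif) {
  assert_that(is_number(Ktrans) && Ktrans >= 0, "Ktrans must be >= 0")
  assert_that(is_number(ve) && ve > 0 && ve <= 1, "ve must lie in (0, 1]")
  if (Ktrans == 0) return(numeric(length(times)))
  .tofts_conv(times, aif$times, aif$Cp, Ktrans, Ktrans / ve)
}

# Smaller eigenvalue of the 2x2 two-site-exchange relaxation matrix.
.fxr_eigenvalue <- function(R1i, kie, R1e, kei) {
  0.5 * ((R1i + kie + R1e + kei) -
           sqrt((R1i + kie - R1e - kei)^2 + 4 * kie * kei))
}

#' FXR (shutter-speed) observable R1 time course
#'
#' Tissue concentration follows the Tofts model; the extracellular rate is
#' `R1e(t) = R10e + r1 Ce(t)` with `Ce = Ct/ve`, and the observable R1 is the
#' smaller eigenvalue of the two-site water exchange matrix
#' \deqn{R_1(t) = \tfrac12[(R_{1i}+k_{ie}+R_{1e}+k_{ei}) -
#'   \sqrt{(R_{1i}+k_{ie}-R_{1e}-k_{ei})^2 + 4 k_{ie} k_{ei}}],}
#' with `kie = 1/tau_i` and detailed balance `kei = kie (1-ve)/ve`.
#' As `tau_i -> 0` this reduces to the fast-exchange-limit linear relation.
#'
#' @param times seconds.
#' @param Ktrans min^-1; @param ve fraction in (0, 1]; @param tau_i seconds.
#' @param aif arterial input, list with `times`, `Cp`.
#' @param R1i precontrast intracellular rate (s^-1).
#' @param R10e precontrast extracellular rate (s^-1).
#' @param r1 relaxivity (mM^-1 s^-1).
#' @return R1 (s^-1) at `times`.
#' @export
fxr_R1 <- function(times, Ktrans, ve, tau_i, aif, R1i, R10e,
                   r1 = QMRI_R1_RELAXIVITY) {
  assert_that(is_number(ve) && ve > 0 && ve <= 1,
              "ve must lie in (0, 1] (kei undefined at ve = 0)")
  assert_that(is_number(tau_i) && tau_i > 0, "tau_i must be positive")
  Ct <- tofts_concentration(times, Ktrans, ve, aif)
  .fxr_R1_from_ct(Ct, ve, tau_i, R1i, R10e, r1)
}

.fxr_R1_from_ct <- function(Ct, ve, tau_i, R1i, R10e, r1) {
  kie <- 1 / tau_i
  kei <- kie * (1 - ve) / ve
  R1e <- R10e + r1 * Ct / ve
  .fxr_eigenvalue(R1i, kie, R1e, kei)
}

#' Fit the FXR model to an R1 time course
#'
#' Box-constrained nonlinear least squares over (Ktrans, ve, tau_i) on the
#' observable R1(t); R1i and R10e default to the measured precontrast tissue
#' rate R10. A Tofts fit of the fast-exchange-limit concentration provides
#' the starting Ktrans and ve; tau_i is multi-started.
#'
#' @param times seconds; @param r1_series observed R1 (s^-1) at `times`.
#' @param aif arterial input; @param R10 precontrast tissue rate (s^-1).
#' @param config list: optional `R1i`, `R10e` (default R10), `r1`, bounds
#'   `Ktrans` (min^-1), `ve`, `tau_i` (s).
#' @return list with `Ktrans` (min^-1), `ve`, `tau_i` (s), `kep` (min^-1),
#'   `rss`, `converged`, `fxl_degenerate` (tau_i at its lower bound).
#' @export
fit_fxr <- function(times, r1_series, aif, R10, config = list()) {
  R1i <- config$R1i %||% R10
  R10e <- config$R10e %||% R10
  r1 <- config$r1 %||% QMRI_R1_RELAXIVITY
  bK <- config$Ktrans %||% c(1e-4, 5)
  bv <- config$ve %||% c(1e-3, 1)
  bt <- config$tau_i %||% c(1e-3, 10)

  ok <- is.finite(r1_series)
  tt <- times[ok]
  robs <- r1_series[ok]

  # FXL initializer: invert Eq. 3 and fit Tofts on the implied concentration.
  ct0 <- pmax((robs - R10) / r1, 0)
  ini <- fit_tofts(tt, ct0, aif, bounds = list(Ktrans = bK, ve = bv))

  lower <- c(bK[1], bv[1], bt[1])
  upper <- c(bK[2], bv[2], bt[2])
  resid_fn <- function(p) {
    Ct <- .tofts_conv(tt, aif$times, aif$Cp, p[1], p[1] / p[2])
    robs - .fxr_R1_from_ct(Ct, p[2], p[3], R1i, R10e, r1)
  }
  best <- NULL
  for (tau0 in c(0.1, 0.5, 1.0)) {
    p0 <- pmin(pmax(c(ini$Ktrans, ini$ve, tau0), lower), upper)
    o <- .lm_box(p0, resid_fn, lower, upper)
    if (is.null(best) || o$rss < best$rss) best <- o
    if (best$rss < 1e-16 * sum(robs^2)) break
  }
  p <- best$par
  list(Ktrans = p[1], ve = p[2], tau_i = p[3], kep = p[1] / p[2],
       rss = best$rss, converged = best$converged,
       fxl_degenerate = p[3] <= lower[3] * (1 + 1e-3))
}

#' Fit the standard Tofts model to a tissue concentration curve
#'
#' @param times seconds; @param ct_series tissue concentration (mM).
#' @param aif arterial input list (`times`, `Cp`).
#' @param bounds optional list with `Ktrans` (min^-1) and `ve` ranges.
#' @return list with `Ktrans` (min^-1), `ve`, `kep` (min^-1), `rss`,
#'   `converged`.
#' @export
fit_tofts <- function(times, ct_series, aif, bounds = list()) {
  bK <- bounds$Ktrans %||% c(1e-4, 5)
  bv <- bounds$ve %||% c(1e-3, 1)
  ok <- is.finite(ct_series)
  tt <- times[ok]
  ct <- ct_series[ok]
  if (all(ct == 0)) {
    return(list(Ktrans = 0, ve = bv[1], kep = 0, rss = 0, converged = TRUE))
  }
  resid_fn <- function(p) ct - .tofts_conv(tt, aif$times, aif$Cp,
                                           p[1], p[1] / p[2])
  lower <- c(bK[1], bv[1])
  upper <- c(bK[2], bv[2])
  best <- NULL
  for (p0 in list(c(0.2, 0.3), c(0.5, 0.6), c(0.05, 0.1))) {
    o <- .lm_box(pmin(pmax(p0, lower), upper), resid_fn, lower, upper)
    if (is.null(best) || o$rss < best$rss) best <- o
    if (best$rss < 1e-16 * sum(ct^2)) break
  }
  p <- best$par
  list(Ktrans = p[1], ve = p[2], kep = p[1] / p[2], rss = best$rss,
       converged = best$converged)
}

#' Parametric population arterial input function
#'
#' Zero before bolus arrival `t0`, a linear upslope over one temporal frame,
#' then biexponential decay
#' \eqn{C_p(t) = ramp(t) [A_1 e^{-m_1 (t-t_0)} + A_2 e^{-m_2 (t-t_0)}]}.
#' Defaults give a ~5 mM peak and a finite area under the curve.
#'
#' @param times seconds.
#' @param t0 bolus arrival (s).
#' @param A amplitudes (mM), length 2.
#' @param m decay rates (s^-1), length 2.
#' @param ramp_dt upslope duration (s), one temporal frame by default.
#' @return list with `times`, `Cp` (mM) and attribute-free plain vectors.
#' @export
population_aif <- function(times, t0 = 40, A = c(4, 1),
                           m = c(1 / 60, 1 / 600), ramp_dt = 8) {
  assert_that(t0 >= min(times) && t0 <= max(times),
              "t0 must lie within the time range")
  u <- times - t0
  ramp <- pmin(pmax(u / ramp_dt, 0), 1)
  Cp <- ramp * (A[1] * exp(-m[1] * pmax(u, 0)) + A[2] * exp(-m[2] * pmax(u, 0)))
  Cp[u < 0] <- 0
  list(times = times, Cp = Cp, t0 = t0, A = A, m = m, ramp_dt = ramp_dt)
}

#' Arterial input function from an arterial ROI signal
#'
#' Converts the arterial mean dynamic signal to blood R1 (via the SPGR
#' inversion and blood R10 = 1/blood_T10), then to whole-blood concentration
#' (linear relaxivity relation), then to plasma concentration
#' `Cp = Cb / (1 - hematocrit)`.
#'
#' @param signals arterial mean signal per phase; @param times seconds.
#' @param n_baseline precontrast phases.
#' @param blood_T10 s; @param hematocrit fraction in [0, 1).
#' @param alpha degrees; @param TR ms; @param r1 mM^-1 s^-1.
#' @return list with `times`, `Cp` (mM), `valid` flags.
#' @export
aif_from_roi <- function(signals, times, n_baseline,
                         blood_T10 = QMRI_BLOOD_T10,
                         hematocrit = QMRI_HEMATOCRIT,
                         alpha = QMRI_FA_DYN, TR = QMRI_TR_MS,
                         r1 = QMRI_R1_RELAXIVITY) {
  assert_that(hematocrit >= 0 && hematocrit < 1,
              "hematocrit must lie in [0, 1)")
  R10b <- 1 / blood_T10
  conv <- dynamic_signal_to_R1(signals, n_baseline, R10b, alpha, TR)
  Cb <- concentration_from_R1(conv$R1, R10b, r1)$Ct
  list(times = times, Cp = Cb / (1 - hematocrit), valid = conv$valid)
}
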