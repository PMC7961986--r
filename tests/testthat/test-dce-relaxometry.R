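times50 <- seq(0, 49 * 8, by = 8)

test_that("spgr_signal matches its closed form and scale invariance", {
  expect_equal(spgr_signal(1.0, 1, 15, 7), 0.04424, tolerance = 1e-4)
  # saturation: E1 -> 0 gives M0 sin(alpha)
  expect_equal(spgr_signal(5000, 2, 89.9, 7), 2 * sin(89.9 * pi / 180),
               tolerance = 1e-3)
  # signal ratio between two angles is independent of M0
  r1 <- spgr_signal(0.8, 1, 30) / spgr_signal(0.8, 1, 5)
  r2 <- spgr_signal(0.8, 77, 30) / spgr_signal(0.8, 77, 5)
  expect_equal(r1, r2, tolerance = 1e-12)
})

test_that("fit_t10_vfa round-trips and flags degenerate input", {
  sig <- vapply(c(30, 15, 5), function(a) spgr_signal(1, 1, a, 7), numeric(1))
  ft <- fit_t10_vfa(sig)
  expect_equal(ft$T10, 1.0, tolerance = 1e-9)
  expect_equal(ft$M0, 1.0, tolerance = 1e-9)
  expect_error(fit_t10_vfa(c(0, 0, 0)), "all-zero")
  expect_error(fit_t10_vfa(c(1, 2), c(15)), "equal length")
})

test_that("fit_t10_vfa median error < 2% at SNR 100 over 1000 voxels", {
  set.seed(12)
  n <- 1000
  t10 <- runif(n, 0.5, 2.5)
  # per-sample SNR 100 (each measurement carries 1% Gaussian noise)
  errs <- vapply(seq_len(n), function(i) {
    sig <- vapply(c(30, 15, 5), function(a)
      spgr_signal(1 / t10[i], 1000, a, 7), numeric(1))
    sig <- sig + rnorm(3, 0, sig / 100)
    ft <- fit_t10_vfa(sig)
    abs(ft$T10 - t10[i]) / t10[i]
  }, numeric(1))
  expect_lt(median(errs, na.rm = TRUE), 0.02)
})

test_that("dynamic SPGR inversion is exact and flags non-physical phases", {
  base <- spgr_signal(1.0, 5, 15, 7)
  conv <- dynamic_signal_to_R1(rep(base, 20), 5, 1.0)
  expect_equal(conv$R1, rep(1.0, 20), tolerance = 1e-12)

  ramp <- seq(1, 4, length.out = 30)
  sig <- c(rep(base, 5), spgr_signal(ramp, 5, 15, 7))
  conv <- dynamic_signal_to_R1(sig, 5, 1.0)
  expect_lt(max(abs(conv$R1[6:35] - ramp)), 1e-9)

  # a signal above the SPGR asymptote M0 sin(alpha) has no valid E1
  expect_message(
    conv <- dynamic_signal_to_R1(c(rep(base, 5), 5 * sin(15 * pi / 180) * 1.1),
                                 5, 1.0),
    "outside the SPGR")
  expect_false(conv$valid[6])
  expect_true(is.na(conv$R1[6]))
})

test_that("concentration_from_R1 is the linear inverse of the forward relation", {
  expect_equal(concentration_from_R1(1.0, 1.0)$Ct, 0)
  expect_equal(concentration_from_R1(3.0, 1.0, 4.0)$Ct, 0.5)
  ct <- runif(20, 0, 2)
  back <- concentration_from_R1(1.2 + 4.0 * ct, 1.2, 4.0)
  expect_equal(back$Ct, ct, tolerance = 1e-12)
  clip <- concentration_from_R1(c(0.9, 1.1), 1.0)
  expect_equal(clip$Ct[1], 0)
  expect_true(clip$clipped[1] && !clip$clipped[2])
})

test_that("tofts_concentration matches closed forms", {
  expect_equal(tofts_concentration(times50, 0, 0.3,
                                   list(times = times50, Cp = rep(1, 50))),
               numeric(50))
  # constant Cp from t = 0: Ct = ve c (1 - exp(-kep t))
  ct <- tofts_concentration(times50, 0.3, 0.3,
                            list(times = times50, Cp = rep(1, 50)))
  kep <- 0.3 / 0.3 / 60
  expected <- 0.3 * (1 - exp(-kep * times50))
  expect_lt(max(abs(ct[-1] - expected[-1]) / expected[-1]), 1e-3)
  expect_equal(ct[50], 0.3, tolerance = 5e-3)  # plateau at ve * c

  # biexponential AIF vs analytic convolution, densely sampled input
  td <- seq(0, 400, by = 1)
  A <- c(4, 1)
  m <- c(1 / 60, 1 / 600)
  aif <- list(times = td, Cp = A[1] * exp(-m[1] * td) + A[2] * exp(-m[2] * td))
  Kt <- 0.39
  ve <- 0.44
  keps <- Kt / ve / 60
  out_t <- seq(0, 400, by = 8)
  analytic <- vapply(out_t, function(t)
    Kt / 60 * sum(A * (exp(-m * t) - exp(-keps * t)) / (keps - m)), numeric(1))
  num <- tofts_concentration(out_t, Kt, ve, aif)
  expect_lt(max(abs(num[-1] - analytic[-1]) / analytic[-1]), 1e-3)
})

test_that("fxr_R1 reproduces the two-site-exchange eigenvalue and its limits", {
  # worked value: Ct = 0.5 mM, ve = 0.3, tau_i = 0.8 s, R1i = R10e = 1.0
  expect_equal(qmritk:::.fxr_R1_from_ct(0.5, 0.3, 0.8, 1.0, 1.0, 4.0),
               1.8333, tolerance = 1e-4)
  # the fast-exchange-limit value at the same concentration is higher
  expect_equal(1.0 + 4.0 * 0.5, 3.0)

  aif <- population_aif(times50, t0 = 40)
  # zero concentration: eigenvalue collapses to R10
  expect_equal(fxr_R1(times50, 0.39, 0.44, 0.8, list(times = times50,
                                                     Cp = numeric(50)),
                      1.0, 1.0),
               rep(1.0, 50), tolerance = 1e-12)
  # fast-exchange limit reduces to the linear relation
  ct <- tofts_concentration(times50, 0.39, 0.44, aif)
  r1 <- fxr_R1(times50, 0.39, 0.44, 1e-6, aif, 1.0, 1.0)
  expect_lt(max(abs(r1 - (1.0 + 4.0 * ct))), 1e-4)
  expect_error(fxr_R1(times50, 0.39, 0, 0.8, aif, 1, 1), "ve")
})

test_that("fxr_R1 obeys ordering, monotonicity and unit-scaling properties", {
  ve <- 0.3
  tau <- 0.8
  cts <- seq(0, 2, by = 0.1)
  r1 <- vapply(cts, function(ct)
    qmritk:::.fxr_R1_from_ct(ct, ve, tau, 1.0, 1.0, 4.0), numeric(1))
  # below the population-weighted fast-exchange value
  pop <- (1 - ve) * 1.0 + ve * (1.0 + 4.0 * cts / ve)
  expect_true(all(r1 <= pop + 1e-12))
  # non-decreasing in Ct
  expect_true(all(diff(r1) >= -1e-12))
  # doubling every rate (R1i, R10e, exchange, relaxivity) doubles the
  # eigenvalue; the dimensionless parameter ve is untouched
  r1_scaled <- vapply(cts, function(ct)
    qmritk:::.fxr_R1_from_ct(ct, ve, tau / 2, 2.0, 2.0, 8.0), numeric(1))
  expect_equal(r1_scaled, 2 * r1, tolerance = 1e-12)
})

test_that("fit_fxr recovers noiseless truth and detects the FXL-degenerate case", {
  aif <- population_aif(times50, t0 = 40)
  truth <- c(Ktrans = 0.39, ve = 0.44, tau_i = 0.71)
  r1 <- fxr_R1(times50, truth[1], truth[2], truth[3], aif, 1.0, 1.0)
  ft <- fit_fxr(times50, r1, aif, R10 = 1.0)
  expect_true(all(abs(c(ft$Ktrans, ft$ve, ft$tau_i) - truth) / truth < 5e-3))
  expect_false(ft$fxl_degenerate)

  # data generated under the fast-exchange (Tofts) limit
  ct <- tofts_concentration(times50, 0.29, 0.23, aif)
  r1_fxl <- 1.0 + 4.0 * ct
  ffxr <- fit_fxr(times50, r1_fxl, aif, R10 = 1.0)
  ftof <- fit_tofts(times50, ct, aif)
  expect_true(ffxr$fxl_degenerate)
  expect_lt(abs(ffxr$Ktrans - ftof$Ktrans) / ftof$Ktrans, 0.01)
  expect_lt(abs(ffxr$ve - ftof$ve) / ftof$ve, 0.01)
})

test_that("fit_fxr noisy-series median errors stay within stated bounds", {
  set.seed(3)
  aif <- population_aif(times50, t0 = 40)
  truth <- c(0.39, 0.44, 0.71)
  clean <- fxr_R1(times50, truth[1], truth[2], truth[3], aif, 1.0, 1.0)
  errs <- t(vapply(1:100, function(i) {
    ft <- fit_fxr(times50, clean + rnorm(50, 0, 0.05), aif, R10 = 1.0)
    abs(c(ft$Ktrans, ft$ve, ft$tau_i) - truth) / truth
  }, numeric(3)))
  med <- apply(errs, 2, median)
  expect_lt(med[1], 0.10)
  expect_lt(med[2], 0.10)
  expect_lt(med[3], 0.25)
})

test_that("fit_tofts round-trips and keeps the kep identity", {
  aif <- population_aif(times50, t0 = 40)
  ct <- tofts_concentration(times50, 0.29, 0.23, aif)
  ft <- fit_tofts(times50, ct, aif)
  expect_lt(abs(ft$Ktrans - 0.29) / 0.29, 1e-3)
  expect_lt(abs(ft$ve - 0.23) / 0.23, 1e-3)
  expect_equal(ft$kep, ft$Ktrans / ft$ve)
  zero <- fit_tofts(times50, numeric(50), aif)
  expect_equal(zero$Ktrans, 0)
})

test_that("population_aif is causal with the correct analytic area", {
  t <- seq(0, 3600, by = 1)
  aif <- population_aif(t, t0 = 40, A = c(4, 1), m = c(1 / 60, 1 / 600),
                        ramp_dt = 8)
  expect_true(all(aif$Cp[t < 40] == 0))
  expect_lt(aif$Cp[length(t)], 0.01)   # decays towards zero
  # analytic AUC: ramp segment + decay tails
  A <- c(4, 1); m <- c(1 / 60, 1 / 600); dt <- 8
  ramp_int <- sum(A / dt * (1 - exp(-m * dt) * (1 + m * dt)) / m^2)
  tail_int <- sum(A * exp(-m * dt) / m) -
    sum(A * exp(-m * (3600 - 40)) / m)
  auc_quad <- sum((aif$Cp[-1] + aif$Cp[-length(t)]) / 2)
  expect_lt(abs(auc_quad - (ramp_int + tail_int)) / (ramp_int + tail_int),
            0.005)
})

test_that("aif_from_roi inverts a known plasma curve", {
  hct <- 0.45
  cp_true <- population_aif(times50, t0 = 40)$Cp
  cb <- cp_true * (1 - hct)
  R10b <- 1 / 1.65
  sig <- spgr_signal(R10b + 4.0 * cb, 800, 15, 7)
  aif <- aif_from_roi(sig, times50, n_baseline = 5)
  expect_lt(max(abs(aif$Cp - cp_true)) / max(cp_true), 0.01)
  expect_equal(aif$Cp[1:5], rep(0, 5), tolerance = 1e-9)
  # zero hematocrit returns whole-blood concentration
  aif0 <- aif_from_roi(sig, times50, n_baseline = 5, hematocrit = 0)
  expect_equal(aif0$Cp, aif$Cp * (1 - hct), tolerance = 1e-9)
})
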