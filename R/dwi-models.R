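#' Diffusion signal models and voxelwise fitting
#'
#' Forward models and least-squares fitting for trace-weighted
#' diffusion-weighted MRI: the monoexponential apparent diffusion coefficient
#' (ADC) model and the non-Gaussian intravoxel incoherent motion (NGIVIM)
#' model, which augments the two-compartment IVIM signal equation with a
#' kurtosis correction of the tissue compartment,
#' \deqn{S(b) = S_0 [ f e^{-b D^*} + (1-f) e^{-b D + \frac{1}{6} K (bD)^2} ].}
#'
#' @name dwi_models
NULL

# Default b-value ladder of the emulated acquisition (s/mm^2).
QMRI_B_VALUES <- c(0, 20, 50, 80, 200, 300, 500, 800, 1500, 2000)

# Fit bounds enclosing published head-and-neck tumor values with wide margin.
NGIVIM_BOUNDS <- list(
  D     = c(1e-5, 3e-3),   # mm^2/s
  Dstar = c(1e-5, 0.1),    # mm^2/s, additionally Dstar >= D
  f     = c(0, 1),
  K     = c(0, 3)
)

#' A single voxel's diffusion signal over a b-value ladder
#'
#' @param b_values strictly increasing diffusion weightings (s/mm^2), first 0.
#' @param signals non-negative signal magnitudes, same length.
#' @return an object of class `bvalue_series`.
#' @export
bvalue_series <- function(b_values, signals) {
  b_values <- as.numeric(b_values)
  signals <- as.numeric(signals)
  assert_that(length(b_values) == length(signals),
              "b_values and signals must have equal length (%d vs %d)",
              length(b_values), length(signals))
  assert_that(length(b_values) >= 2 && b_values[1] == 0,
              "b_values must start at 0")
  assert_that(all(diff(b_values) > 0), "b_values must be strictly increasing")
  assert_that(all(is.finite(signals)) && all(signals >= 0),
              "signals must be finite and non-negative")
  structure(list(b_values = b_values, signals = signals),
            class = "bvalue_series")
}

#' Monoexponential diffusion signal
#'
#' \eqn{S(b) = S_0 e^{-b \cdot ADC}}.
#'
#' @param b diffusion weighting (s/mm^2), vectorized, `>= 0`.
#' @param S0 signal without diffusion weighting, `> 0`.
#' @param ADC apparent diffusion coefficient (mm^2/s), `>= 0`.
#' @return signal magnitude(s) in `(0, S0]`.
#' @export
monoexp_signal <- function(b, S0, ADC) {
  assert_that(all(b >= 0), "b must be non-negative")
  assert_that(is_number(S0) && S0 > 0, "S0 must be a positive number")
  assert_that(is_number(ADC) && ADC >= 0, "ADC must be non-negative")
  S0 * exp(-b * ADC)
}

#' Non-Gaussian IVIM diffusion signal
#'
#' Two-compartment pseudo-diffusion/tissue model with a kurtosis term in the
#' tissue exponent:
#' \eqn{S(b) = S_0 [f e^{-b D^*} + (1-f) e^{-b D + \frac{1}{6}K(bD)^2}]}.
#'
#' @param b diffusion weighting (s/mm^2), vectorized, `>= 0`.
#' @param S0 unweighted signal, `> 0`.
#' @param f perfusion (pseudo-diffusion) fraction in `[0, 1]`.
#' @param D true diffusion coefficient (mm^2/s), `0 < D <= Dstar`.
#' @param Dstar pseudo-diffusion coefficient (mm^2/s).
#' @param K kurtosis coefficient, `>= 0`.
#' @export
ngivim_signal <- function(b, S0, f, D, Dstar, K) {
  assert_that(all(b >= 0), "b must be non-negative")
  assert_that(is_number(S0) && S0 > 0, "S0 must be a positive number")
  assert_that(is_number(f) && f >= 0 && f <= 1, "f must lie in [0, 1]")
  assert_that(is_number(D) && D > 0, "D must be positive")
  assert_that(is_number(Dstar) && Dstar >= D, "Dstar must satisfy Dstar >= D")
  assert_that(is_number(K) && K >= 0, "K must be non-negative")
  S0 * (f * exp(-b * Dstar) + (1 - f) * exp(-b * D + (1 / 6) * K * (b * D)^2))
}

# Unvalidated fast path used inside optimizers.
.ngivim_model <- function(b, S0, f, D, Dstar, K) {
  S0 * (f * exp(-b * Dstar) + (1 - f) * exp(-b * D + (1 / 6) * K * (b * D)^2))
}

# Analytic d model / d (S0, f, D, dD, K) with Dstar = D + dD.
.ngivim_jacobian <- function(b, p) {
  S0 <- p[1]; f <- p[2]; D <- p[3]; dD <- p[4]; K <- p[5]
  e1 <- exp(-b * (D + dD))
  e2 <- exp(-b * D + (1 / 6) * K * (b * D)^2)
  cbind(f * e1 + (1 - f) * e2,
        S0 * (e1 - e2),
        S0 * (f * (-b) * e1 + (1 - f) * e2 * (-b + (1 / 3) * K * b^2 * D)),
        S0 * f * (-b) * e1,
        S0 * (1 - f) * e2 * (1 / 6) * b^2 * D^2)
}

#' Fit the monoexponential ADC model to one voxel
#'
#' Log-linear regression of `log(signal)` on b provides the estimate
#' (exact for noiseless data); a bounded nonlinear refinement on the
#' untransformed signal follows, so the reported estimate minimizes the
#' unweighted residual sum of squares in signal space.
#'
#' @param series a [bvalue_series()].
#' @param b_subset optional b-values (s/mm^2) to restrict the fit to; by
#'   default all b-values enter the ADC fit.
#' @return list with `S0`, `ADC` (mm^2/s), `rss`, `converged`, `message`.
#' @export
fit_adc <- function(series, b_subset = NULL) {
  stopifnot(inherits(series, "bvalue_series"))
  b <- series$b_values
  s <- series$signals
  if (!is.null(b_subset)) {
    keep <- b %in% b_subset
    assert_that(any(b[keep] == 0), "b_subset must retain b = 0")
    b <- b[keep]
    s <- s[keep]
  }
  assert_that(length(b) >= 4, "ADC fitting needs >= 4 b-values (have %d)",
              length(b))

  if (all(s == 0)) {
    return(list(S0 = NA_real_, ADC = NA_real_, rss = NA_real_,
                converged = FALSE, message = "all-zero signal"))
  }
  if (diff(range(s)) == 0) {
    # Flat nonzero decay: boundary estimate ADC = 0.
    return(list(S0 = s[1], ADC = 0, rss = 0, converged = FALSE,
                message = "constant signal; ADC at lower boundary 0"))
  }

  pos <- s > 0
  if (sum(pos) < 2) {
    return(list(S0 = NA_real_, ADC = NA_real_, rss = NA_real_,
                converged = FALSE, message = "too few positive signals"))
  }
  co <- stats::coef(stats::lm(log(s[pos]) ~ b[pos]))
  S0_0 <- exp(unname(co[1]))
  ADC_0 <- max(0, -unname(co[2]))

  lower <- c(1e-12, 0)
  upper <- c(10 * max(s), 0.1)
  resid_fn <- function(p) s - p[1] * exp(-b * p[2])
  jac_fn <- function(p) {
    e <- exp(-b * p[2])
    cbind(e, -p[1] * b * e)
  }
  o <- .lm_box(pmin(pmax(c(S0_0, ADC_0), lower), upper), resid_fn,
               lower, upper, jac_fn = jac_fn)
  list(S0 = o$par[1], ADC = o$par[2], rss = o$rss,
       converged = o$converged, message = "")
}

# Segmented initialization: quadratic log-signal regression on the high-b
# ladder gives (S0_t, D, K); the low-b residual gives (f, Dstar).
.ngivim_init <- function(b, s, b_split) {
  hi <- b >= b_split & s > 0
  lo <- b < b_split
  bh <- b[hi]; sh <- s[hi]
  co <- stats::coef(stats::lm(log(sh) ~ bh + I(bh^2)))
  D0 <- min(max(-unname(co[2]), NGIVIM_BOUNDS$D[1]), NGIVIM_BOUNDS$D[2])
  K0 <- if (D0 > 0) 6 * unname(co[3]) / D0^2 else 0
  K0 <- min(max(K0, 0), NGIVIM_BOUNDS$K[2])
  tissue0 <- exp(unname(co[1]))                 # S0 * (1 - f)

  # Perfusion compartment from the low-b residual above the tissue curve.
  resid <- s[lo] - tissue0 * exp(-b[lo] * D0 + (1 / 6) * K0 * (b[lo] * D0)^2)
  if (max(resid) <= 0) {
    f0 <- 0
    Dstar0 <- max(NGIVIM_BOUNDS$Dstar[1], D0)
    S00 <- tissue0
  } else {
    amp0 <- max(resid[b[lo] == 0], max(resid))  # ~ S0 * f
    pos <- lo & (s - tissue0 * exp(-b * D0 + (1 / 6) * K0 * (b * D0)^2)) > 0
    rp <- s[pos] - tissue0 * exp(-b[pos] * D0 + (1 / 6) * K0 * (b[pos] * D0)^2)
    Dstar0 <- if (sum(pos) >= 2) {
      cs <- stats::coef(stats::lm(log(rp) ~ b[pos]))
      min(max(-unname(cs[2]), D0), NGIVIM_BOUNDS$Dstar[2])
    } else 10e-3
    S00 <- tissue0 + amp0
    f0 <- min(max(amp0 / S00, 0), 0.5)
  }
  c(S0 = S00, f = f0, D = D0, dD = max(Dstar0 - D0, 0), K = K0)
}

#' Fit the NGIVIM model to one voxel
#'
#' Three-stage procedure: (1) D, K and the tissue amplitude from a quadratic
#' log-signal regression on b >= `b_split` where the pseudo-diffusion
#' compartment has decayed; (2) f and D* from the low-b residual signal;
#' (3) joint bounded nonlinear least squares over all five parameters.
#' D* is parameterized as D + delta (delta >= 0) so the ordering invariant
#' D <= D* holds at every iterate.
#'
#' @param series a [bvalue_series()] with at least 6 b-values spanning both
#'   sides of `b_split`.
#' @param config list; `b_split` (s/mm^2, default 200) and optional `bounds`
#'   overriding [NGIVIM_BOUNDS] entries.
#' @return list with `S0`, `f`, `D`, `Dstar`, `K`, `rss`, `converged`,
#'   `boundary` (TRUE when f or K sits on a constraint), `message`.
#' @export
fit_ngivim <- function(series, config = list()) {
  stopifnot(inherits(series, "bvalue_series"))
  b <- series$b_values
  s <- series$signals
  b_split <- config$b_split %||% 200
  bounds <- utils::modifyList(NGIVIM_BOUNDS, config$bounds %||% list())
  assert_that(length(b) >= 6, "NGIVIM fitting needs >= 6 b-values")
  assert_that(sum(b < b_split) >= 2 && sum(b >= b_split) >= 3,
              "b-values must span both sides of b_split = %g", b_split)

  if (all(s == 0) || diff(range(s)) == 0) {
    return(list(S0 = NA_real_, f = NA_real_, D = NA_real_, Dstar = NA_real_,
                K = NA_real_, rss = NA_real_, converged = FALSE,
                boundary = FALSE, message = "degenerate signal"))
  }

  seg <- .ngivim_init(b, s, b_split)
  smax <- max(s)
  lower <- c(1e-9, bounds$f[1], bounds$D[1], 0, bounds$K[1])
  upper <- c(10 * smax, bounds$f[2], bounds$D[2],
             bounds$Dstar[2], bounds$K[2])
  resid_fn <- function(p)
    s - .ngivim_model(b, p[1], p[2], p[3], p[3] + p[4], p[5])
  jac_fn <- function(p) .ngivim_jacobian(b, p)

  # The segmented start fails when D* is close to D (compartments barely
  # separated), so refine from a small fixed bank of pseudo-diffusion starts
  # and keep the best local optimum.
  starts <- list(pmin(pmax(unname(seg), lower), upper))
  for (f0 in c(0.05, 0.2)) {
    for (dD0 in c(0.5e-3, 1.5e-3, 8e-3, 40e-3)) {
      starts <- c(starts, list(c(s[1], f0, seg[["D"]], dD0,
                                 max(seg[["K"]], 0.5))))
    }
  }
  best <- NULL
  for (p0 in starts) {
    o <- .lm_box(pmin(pmax(p0, lower), upper), resid_fn, lower, upper,
                 jac_fn = jac_fn)
    if (is.null(best) || o$rss < best$rss) best <- o
    if (best$rss < 1e-18 * sum(s^2)) break   # at the noiseless floor
  }
  p <- best$par
  boundary <- p[2] <= lower[2] + 1e-8 || p[5] <= lower[5] + 1e-8 ||
    p[2] >= upper[2] - 1e-8
  list(S0 = p[1], f = p[2], D = p[3], Dstar = p[3] + p[4], K = p[5],
       rss = best$rss, converged = best$converged,
       boundary = boundary, message = "")
}

#' Fit a diffusion model voxelwise over a masked 4D volume
#'
#' @param volume 4D array; 4th axis indexes the b-value ladder.
#' @param mask 3D logical (or 0/1) array on the same grid.
#' @param b_values b-value ladder matching `dim(volume)[4]`.
#' @param model `"monoexp"` or `"ngivim"`.
#' @param config passed to the per-voxel fitter.
#' @return named list of `parametric_map` objects (3D arrays, `NA` outside
#'   the mask and at failed voxels) plus a `converged` count attribute.
#' @export
fit_volume <- function(volume, mask, b_values = QMRI_B_VALUES,
                       model = c("monoexp", "ngivim"), config = list()) {
  model <- match.arg(model)
  assert_that(length(dim(volume)) == 4, "volume must be 4D")
  assert_that(dim(volume)[4] == length(b_values),
              "4th axis (%d) must match the b-value ladder (%d)",
              dim(volume)[4], length(b_values))
  assert_that(identical(dim(mask), dim(volume)[1:3]),
              "mask grid does not match volume grid")
  mask <- array(as.logical(mask), dim = dim(mask))

  params <- if (model == "monoexp") c("S0", "ADC") else
    c("S0", "f", "D", "Dstar", "K")
  maps <- lapply(params, function(p)
    array(NA_real_, dim = dim(mask)))
  names(maps) <- params

  idx <- which(mask)
  if (length(idx) == 0) {
    warning("empty mask: no voxels fitted")
    return(structure(lapply(maps, parametric_map, mask = mask),
                     n_fitted = 0L, n_failed = 0L))
  }
  nxyz <- prod(dim(mask))
  flat <- matrix(volume, nrow = nxyz)
  n_fail <- 0L
  for (i in idx) {
    ser <- bvalue_series(b_values, flat[i, ])
    fit <- if (model == "monoexp") fit_adc(ser, config$b_subset) else
      fit_ngivim(ser, config)
    if (isTRUE(fit$converged)) {
      for (p in params) maps[[p]][i] <- fit[[p]]
    } else {
      n_fail <- n_fail + 1L
    }
  }
  qmri_log("fit_volume", "%s: %d voxels fitted, %d failed", model,
           length(idx) - n_fail, n_fail)
  out <- mapply(function(v, nm) parametric_map(v, mask, name = nm),
                maps, names(maps), SIMPLIFY = FALSE)
  structure(out, n_fitted = length(idx) - n_fail, n_failed = n_fail)
}

#' Parametric map container
#'
#' A 3D array of per-voxel estimates defined on a mask; non-mask and failed
#' voxels carry `NA`.
#'
#' @param values 3D numeric array.
#' @param mask 3D logical array, same grid.
#' @param name metric identifier.
#' @export
parametric_map <- function(values, mask, name = "metric") {
  assert_that(identical(dim(values), dim(mask)), "map/mask grid mismatch")
  values[!mask] <- NA_real_
  structure(values, mask = mask, metric = name, class = "parametric_map")
}

#' @export
print.parametric_map <- function(x, ...) {
  v <- x[attr(x, "mask") & !is.na(x)]
  cat(sprintf("<parametric_map> %s: %s grid, %d fitted voxels, mean %.4g\n",
              attr(x, "metric"), paste(dim(x), collapse = "x"),
              length(v), mean(v)))
  invisible(x)
}
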