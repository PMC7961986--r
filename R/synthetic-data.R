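#' Seeded phantom and cohort simulators
#'
#' Generators emulating the acquisition and cohort structure of the studied
#' protocol: a 10-b-value trace-weighted DWI acquisition, a three-angle VFA
#' precontrast series followed by a 50-phase dynamic SPGR series at ~8 s
#' temporal resolution, and a two-cause (locoregional failure, death)
#' outcome process with censoring over a 3-32 month follow-up window. Every
#' generator is a pure function of its arguments and seed. Noise models:
#' Rician for DWI magnitude data, Gaussian for DCE signal.
#'
#' @name synthetic_data
NULL

#' Acquisition configuration
#'
#' @param b_values diffusion ladder (s/mm^2).
#' @param TR_dce dynamic repetition time (ms); @param alpha_dce degrees.
#' @param vfa_angles degrees; @param n_phases dynamic phases;
#' @param dt temporal resolution (s); @param noise_sd signal noise SD;
#' @param seed mandatory integer seed for stochastic output.
#' @return validated config list.
#' @export
acquisition_config <- function(b_values = QMRI_B_VALUES, TR_dce = QMRI_TR_MS,
                               alpha_dce = QMRI_FA_DYN,
                               vfa_angles = QMRI_VFA_ANGLES, n_phases = 50L,
                               dt = 8, noise_sd = 0, seed = 1L) {
  assert_that(all(b_values >= 0) && b_values[1] == 0,
              "b_values must start at 0")
  assert_that(TR_dce > 0 && alpha_dce > 0 && n_phases >= 10 && dt > 0,
              "acquisition parameters must be positive (n_phases >= 10)")
  assert_that(noise_sd >= 0, "noise_sd must be non-negative")
  assert_that(is_number(seed), "seed is mandatory")
  list(b_values = b_values, TR_dce = TR_dce, alpha_dce = alpha_dce,
       vfa_angles = vfa_angles, n_phases = as.integer(n_phases), dt = dt,
       noise_sd = noise_sd, seed = as.integer(seed))
}

# Rician-distributed magnitude: |signal + complex Gaussian noise|.
.rician <- function(s, sd) {
  if (sd == 0) return(s)
  sqrt((s + stats::rnorm(length(s), 0, sd))^2 +
         stats::rnorm(length(s), 0, sd)^2)
}

#' Simulate a DWI phantom with known NGIVIM truth maps
#'
#' Voxelwise truth parameters are drawn uniformly within physiologic ranges
#' spanning the published tumor values; the noiseless signal follows the
#' NGIVIM forward model and Rician noise of the configured SD is added to
#' each b-value image. Background voxels (outside the mask) have zero true
#' signal, so their high-b magnitudes expose the Rician noise floor.
#'
#' @param config from [acquisition_config()].
#' @param dim3 grid size, default `c(16, 16, 4)`.
#' @param ranges list of truth ranges: `S0`, `f`, `D`, `Dstar`, `K`.
#' @return list: `volume` (4D array), `mask`, `truth` (list of 3D maps),
#'   `b_values`.
#' @export
generate_dwi_phantom <- function(config = acquisition_config(),
                                 dim3 = c(16, 16, 4),
                                 ranges = list(S0 = c(400, 600),
                                               f = c(0.12, 0.24),
                                               D = c(0.5e-3, 1.1e-3),
                                               Dstar = c(2.0e-3, 2.7e-3),
                                               K = c(0.6, 1.2))) {
  withr_seed(config$seed, {
    nb <- length(config$b_values)
    mask <- array(FALSE, dim3)
    # central block tumor ROI
    ix <- seq(max(1, dim3[1] %/% 4), dim3[1] - dim3[1] %/% 4)
    iy <- seq(max(1, dim3[2] %/% 4), dim3[2] - dim3[2] %/% 4)
    mask[ix, iy, ] <- TRUE

    nvox <- prod(dim3)
    truth <- list(
      S0 = array(stats::runif(nvox, ranges$S0[1], ranges$S0[2]), dim3),
      f = array(stats::runif(nvox, ranges$f[1], ranges$f[2]), dim3),
      D = array(stats::runif(nvox, ranges$D[1], ranges$D[2]), dim3),
      Dstar = array(stats::runif(nvox, ranges$Dstar[1], ranges$Dstar[2]),
                    dim3),
      K = array(stats::runif(nvox, ranges$K[1], ranges$K[2]), dim3)
    )
    truth$Dstar <- pmax(truth$Dstar, truth$D)  # ordering invariant
    for (nm in names(truth)) truth[[nm]][!mask] <- NA_real_

    vol <- array(0, c(dim3, nb))
    flat <- matrix(0, nvox, nb)
    idx <- which(mask)
    for (i in idx) {
      flat[i, ] <- .ngivim_model(config$b_values, truth$S0[i], truth$f[i],
                                 truth$D[i], truth$Dstar[i], truth$K[i])
    }
    flat <- matrix(.rician(as.vector(flat), config$noise_sd), nvox, nb)
    vol <- array(flat, c(dim3, nb))
    list(volume = vol, mask = mask, truth = truth,
         b_values = config$b_values)
  })
}

#' Simulate a DCE phantom (VFA + dynamic series) with known truth maps
#'
#' Per voxel: tissue concentration from the Tofts model driven by a
#' parametric arterial input, observable R1(t) from the FXR two-site
#' exchange eigenvalue, and SPGR signal at the dynamic flip angle. The VFA
#' precontrast volumes use the same SPGR model at the three mapping angles.
#' Gaussian noise of the configured SD is added to every signal sample.
#'
#' @param config from [acquisition_config()].
#' @param dim3 grid size.
#' @param ranges truth ranges: `T10` (s), `Ktrans` (min^-1), `ve`, `tau_i`
#'   (s); the precontrast intracellular/extracellular rates are set to
#'   1/T10.
#' @param aif_params passed to [population_aif()] (`t0`, `A`, `m`,
#'   `ramp_dt`).
#' @param M0 equilibrium signal scale.
#' @param n_baseline precontrast phases before bolus arrival.
#' @return list: `vfa` (4D array, one volume per angle), `dynamic` (4D),
#'   `times`, `mask`, `truth`, `aif`, `n_baseline`, `M0`.
#' @export
generate_dce_phantom <- function(config = acquisition_config(),
                                 dim3 = c(16, 16, 4),
                                 ranges = list(T10 = c(0.8, 1.6),
                                               Ktrans = c(0.15, 0.55),
                                               ve = c(0.15, 0.6),
                                               tau_i = c(0.4, 1.2)),
                                 aif_params = list(), M0 = 1000,
                                 n_baseline = 5L) {
  withr_seed(config$seed, {
    times <- (seq_len(config$n_phases) - 1) * config$dt
    t0 <- aif_params$t0 %||% (n_baseline * config$dt)
    aif <- do.call(population_aif, utils::modifyList(
      list(times = times, t0 = t0, ramp_dt = config$dt), aif_params))

    mask <- array(FALSE, dim3)
    ix <- seq(max(1, dim3[1] %/% 4), dim3[1] - dim3[1] %/% 4)
    iy <- seq(max(1, dim3[2] %/% 4), dim3[2] - dim3[2] %/% 4)
    mask[ix, iy, ] <- TRUE

    nvox <- prod(dim3)
    truth <- list(
      T10 = array(stats::runif(nvox, ranges$T10[1], ranges$T10[2]), dim3),
      Ktrans = array(stats::runif(nvox, ranges$Ktrans[1], ranges$Ktrans[2]),
                     dim3),
      ve = array(stats::runif(nvox, ranges$ve[1], ranges$ve[2]), dim3),
      tau_i = array(stats::runif(nvox, ranges$tau_i[1], ranges$tau_i[2]),
                    dim3)
    )
    for (nm in names(truth)) truth[[nm]][!mask] <- NA_real_

    nang <- length(config$vfa_angles)
    vfa <- array(0, c(dim3, nang))
    dyn <- array(0, c(dim3, config$n_phases))
    for (i in which(mask)) {
      R10 <- 1 / truth$T10[i]
      for (k in seq_len(nang)) {
        vfa[arrayInd(i, dim3)[1], arrayInd(i, dim3)[2],
            arrayInd(i, dim3)[3], k] <-
          spgr_signal(R10, M0, config$vfa_angles[k], config$TR_dce)
      }
      r1t <- fxr_R1(times, truth$Ktrans[i], truth$ve[i], truth$tau_i[i],
                    aif, R1i = R10, R10e = R10)
      sdyn <- spgr_signal(r1t, M0, config$alpha_dce, config$TR_dce)
      ijk <- arrayInd(i, dim3)
      dyn[ijk[1], ijk[2], ijk[3], ] <- sdyn
    }
    if (config$noise_sd > 0) {
      vfa <- vfa + array(stats::rnorm(length(vfa), 0, config$noise_sd),
                         dim(vfa))
      dyn <- dyn + array(stats::rnorm(length(dyn), 0, config$noise_sd),
                         dim(dyn))
    }
    list(vfa = vfa, dynamic = dyn, times = times, mask = mask, truth = truth,
         aif = aif, n_baseline = as.integer(n_baseline), M0 = M0)
  })
}

#' Cohort specification for the competing-risks simulator
#'
#' Defaults emulate the published cohort summary values: per-group Gaussian
#' metric distributions truncated to physical ranges, a cause-1
#' (locoregional failure) subdistribution linked to the metric through a
#' stated coefficient, exponential competing mortality among the remainder,
#' and independent uniform censoring over the follow-up window.
#'
#' @param n_with,n_without subjects per group (with/without LRF-like risk
#'   profile).
#' @param metric metric name whose published group values seed the draws.
#' @param beta true subdistribution log-hazard ratio per unit covariate.
#' @param p_event1 baseline probability of the event of interest at
#'   covariate 0.
#' @param rate1 time scale (months^-1) of the cause-1 subdistribution.
#' @param rate2 exponential rate (months^-1) of the competing event.
#' @param follow_up censoring window (months), default `c(3, 32)`.
#' @param censor_prob probability of forced administrative censoring.
#' @param seed integer.
#' @return validated spec list.
#' @export
cohort_spec <- function(n_with = 6L, n_without = 23L, metric = "ve",
                        beta = 0.693, p_event1 = 0.25, rate1 = 0.15,
                        rate2 = 0.03, follow_up = c(3, 32),
                        censor_prob = 0, seed = 1L) {
  assert_that(n_with >= 2 && n_without >= 2, "need >= 2 subjects per group")
  assert_that(p_event1 > 0 && p_event1 < 1, "p_event1 must lie in (0, 1)")
  assert_that(rate1 > 0 && rate2 > 0, "rates must be positive")
  assert_that(censor_prob >= 0 && censor_prob <= 1,
              "censor_prob must lie in [0, 1]")
  list(n_with = as.integer(n_with), n_without = as.integer(n_without),
       metric = metric, beta = beta, p_event1 = p_event1, rate1 = rate1,
       rate2 = rate2, follow_up = follow_up, censor_prob = censor_prob,
       seed = as.integer(seed))
}

# Indirect Fine-Gray simulation (unit-exponential mixture subdistribution):
# P(cause 1 | x) = 1 - (1 - p)^exp(x b); conditional cause-1 times from the
# inverted subdistribution so the true subdistribution coefficient is `beta`;
# cause-2 times exponential among the remainder.
.fg_simulate <- function(x, beta, p, rate1, rate2) {
  n <- length(x)
  ex <- exp(x * beta)
  p1 <- 1 - (1 - p)^ex
  is1 <- stats::rbinom(n, 1, p1) == 1
  time <- numeric(n)
  u <- stats::runif(n)
  # F1(t|x)/p1 = u  =>  t = -log(1 - (1-(1-u*p1)^(1/ex))/p) / rate1
  q <- 1 - (1 - u[is1] * p1[is1])^(1 / ex[is1])
  time[is1] <- -log(1 - q / p) / rate1
  time[!is1] <- stats::rexp(sum(!is1), rate2)
  list(time = time, cause = ifelse(is1, 1L, 2L))
}

#' Simulate a two-cause outcome cohort with known subdistribution effect
#'
#' Metric values are drawn per group from Gaussians with the published
#' means/SDs (truncated to physical range); the standardized, centered
#' metric is the covariate of the cause-1 subdistribution.
#'
#' @param spec from [cohort_spec()].
#' @return data.frame: `subject_id`, `group`, `metric`, `value`,
#'   `time_months`, `event` (0/1/2), plus attribute `truth` carrying the
#'   generating parameters.
#' @export
generate_cohort <- function(spec = cohort_spec()) {
  ref <- npc_reference_metrics()
  row <- ref[ref$metric == spec$metric, ]
  assert_that(nrow(row) == 1, "unknown metric '%s'", spec$metric)
  withr_seed(spec$seed, {
    n <- spec$n_with + spec$n_without
    group <- c(rep("with_LRF", spec$n_with),
               rep("without_LRF", spec$n_without))
    mu <- ifelse(group == "with_LRF", row$mean_with, row$mean_without)
    sdv <- ifelse(group == "with_LRF", row$sd_with, row$sd_without)
    value <- stats::rnorm(n, mu, sdv)
    lo <- if (row$metric %in% c("f", "ve")) 1e-3 else 1e-4
    hi <- if (row$metric %in% c("f", "ve")) 1 else Inf
    value <- pmin(pmax(value, lo), hi)

    # Standardized covariate; lower metric value -> higher cause-1 hazard
    # when beta > 0 and the without-LRF group mean exceeds the with-LRF one.
    xs <- -(value - mean(value)) / stats::sd(value) *
      sign(row$mean_without - row$mean_with)
    sim <- .fg_simulate(xs, spec$beta, spec$p_event1, spec$rate1, spec$rate2)
    cens <- stats::runif(n, spec$follow_up[1], spec$follow_up[2])
    forced <- stats::runif(n) < spec$censor_prob
    time <- pmin(sim$time, cens)
    event <- ifelse(cens < sim$time, 0L, sim$cause)
    event[forced] <- 0L
    time[forced] <- pmin(sim$time, cens)[forced]
    time <- pmax(time, 0.01)

    out <- data.frame(subject_id = sprintf("S%03d", seq_len(n)),
                      group = group, metric = row$metric, value = value,
                      time_months = time, event = event,
                      stringsAsFactors = FALSE)
    attr(out, "truth") <- list(beta = spec$beta, covariate = xs,
                               cause = sim$cause)
    out
  })
}
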