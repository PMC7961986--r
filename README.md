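# qmritk

Quantitative MRI modelling and competing-risks outcome analysis for
head-and-neck tumor imaging.

## The problem

Nasopharyngeal carcinoma (NPC) is treated with definitive chemoradiation, and
a minority of patients go on to locoregional failure (LRF). Pre-treatment
quantitative MRI promises imaging biomarkers of that risk: diffusion-weighted
MRI probes tumor cellularity and microstructure, and dynamic
contrast-enhanced (DCE) MRI probes vessel permeability, extracellular volume
and — through water-exchange-sensitive modelling — cellular metabolic
activity. Because failures are rare and patients also die of other causes,
relating those metrics to outcome requires competing-risks survival
statistics rather than ordinary Kaplan-Meier/Cox analysis.

`qmritk` implements that entire analysis chain as a tested R package:

* **Diffusion** — monoexponential ADC, and the non-Gaussian intravoxel
  incoherent motion (NGIVIM) model
  `S(b) = S0 [ f e^(-b D*) + (1-f) e^(-b D + (1/6) K (bD)^2) ]`,
  fitted voxelwise by segmented initialization plus box-constrained
  Levenberg-Marquardt (parameters: perfusion fraction `f`, true and
  pseudo-diffusion coefficients `D`, `D*`, kurtosis `K`).
* **Relaxometry / DCE** — SPGR signal model, variable flip angle T10
  mapping, signal-to-R1 inversion, the standard Tofts model
  `Ct(t) = Ktrans ∫ Cp(u) e^(-kep (t-u)) du`, and the shutter-speed fast
  exchange regime (FXR) model in which the observable R1(t) is the smaller
  eigenvalue of the two-site transcytolemmal water exchange matrix,
  yielding `Ktrans`, `ve` and the intracellular water lifetime `tau_i`.
* **ROI statistics** — histogram mean/SD/skewness/kurtosis (non-excess
  convention) and group relative-difference summaries.
* **Outcome analysis** — Wilcoxon rank-sum, Youden-index dichotomization,
  Aalen-Johansen cumulative incidence, Gray's test (permutation reference),
  and Fine-Gray subdistribution hazards regression with death as the
  competing risk.
* **Simulators** — seeded DWI/DCE phantoms and two-cause outcome cohorts
  with known ground truth, emulating a 10-b-value ladder
  (0-2000 s/mm²), a 3-angle VFA series plus 50 dynamic phases at 8 s
  resolution (TR 7 ms, FA 15°), and a 3-32 month follow-up window.
* **I/O + CLI** — minimal NIfTI-1 reader/writer, CSV cohort tables, YAML
  configs, and a `qmri_main()` command line with `simulate`, `fit-dwi`,
  `t1map`, `fit-dce`, `roi-stats` and `survival` subcommands.

## Worked example

```r
library(qmritk)

## NGIVIM round trip on the 10-b-value ladder
b <- c(0, 20, 50, 80, 200, 300, 500, 800, 1500, 2000)
sig <- ngivim_signal(b, S0 = 1000, f = 0.19, D = 0.87e-3,
                     Dstar = 2.40e-3, K = 0.82)
fit <- fit_ngivim(bvalue_series(b, sig))
str(fit[c("f", "D", "Dstar", "K")])
#> List of 4
#>  $ f    : num 0.19
#>  $ D    : num 0.00087
#>  $ Dstar: num 0.0024
#>  $ K    : num 0.82

## FXR (shutter-speed) DCE fit on a 50-phase, 8-s series
times <- seq(0, 392, by = 8)
aif <- population_aif(times, t0 = 40)
r1 <- fxr_R1(times, Ktrans = 0.39, ve = 0.44, tau_i = 0.71, aif,
             R1i = 1, R10e = 1)
ffxr <- fit_fxr(times, r1, aif, R10 = 1)
cat(sprintf("Ktrans = %.3f min^-1, ve = %.3f, tau_i = %.3f s\n",
            ffxr$Ktrans, ffxr$ve, ffxr$tau_i))
#> Ktrans = 0.390 min^-1, ve = 0.440, tau_i = 0.710 s

## Competing-risks analysis of a simulated 40-subject cohort
co <- generate_cohort(cohort_spec(n_with = 10, n_without = 30,
                                  beta = 1.0, seed = 7))
run_survival_analysis(co, n_perm = 2000, seed = 7)
#>   metric cutoff direction youden_J gray_stat gray_p  shr ci_low ci_high   fg_p unstable
#> 1     ve  0.507        le    0.335      3.71 0.0505 3.89  0.838      18 0.0828    FALSE
```

The survival table reads: the `ve` values were dichotomized at the
Youden-optimal cutoff 0.507 ("low ve" = `value <= cutoff` predicts failure);
Gray's test for a difference in the cumulative incidence of failure between
the two groups gives p = 0.050; the Fine-Gray subdistribution hazard ratio
of the low-ve group is 3.9 (95% CI 0.84-18, p = 0.083). `unstable` would
flag confidence intervals spanning more than three orders of magnitude, the
signature of small-sample monotone-likelihood behaviour.

## Layout

* `R/` — implementation (diffusion, DCE relaxometry, ROI metrics, outcome
  statistics, simulators, NIfTI/CSV/CLI plumbing)
* `tests/testthat/` — unit, property and acceptance suites with independent
  brute-force/permutation oracles in `helper-oracles.R`
* `vignettes/qmritk-methods.Rmd` — the models, assumptions, numerical
  choices and limitations
* `scripts/acceptance.R` — the acceptance report
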