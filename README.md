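# kdpanel

Spatio-temporal ecological regression for age-stratified disease
surveillance panels, built around the epidemiology of Kawasaki disease
(KD) and its relationship to the total fertility rate (TFR).

KD incidence in Japan has climbed for decades while fertility fell. Under
a catalytic infection model with constant force of infection λ, the mean
age at first infection is A ≈ 1/λ, so the mean age of patients is an
inverse surrogate of the hazard of contracting the (unknown) aetiologic
agent. This package implements the full analysis chain that exploits that
relation on prefecture-level panels:

* **Surveillance metrics** — incidence per 100,000 children aged 0–4,
  directly age-standardized incidence, crude mean patient age
  (case-weighted midpoint mean over a 19-class age scheme), and
  demography-adjusted mean age (counts reweighted by S_k/C_ijk, the
  standard-to-local population share ratio on an 11-class scheme).
* **Box-Cox normalization** with profile-likelihood estimation of the
  power θ, and its exact inverse for reconstruction.
* **Cross-sectional regression** — OLS and maximum-likelihood spatial-lag
  regression Y = ρUY + Xβ + ε on a binary adjacency matrix, with backward
  stepwise elimination at p ≥ 0.05.
* **Time-series regression** — distributed-lag covariates x̄ over
  [j−G−W, j−G+W], a grid search over lag G and smoothing radius W
  maximizing the overall R² of a random-effect AR(1) panel model
  (two-step feasible GLS with Prais–Winsten quasi-differencing), and
  multivariate models at the per-covariate optimal lag specs.
* **Retrograde reconstruction** — the fitted univariate TFR model applied
  to the national TFR series and extrapolated backwards in time.
* **A synthetic surveillance generator** with known ground truth: 47
  lattice regions, spatially autocorrelated covariates, declining TFR
  trajectories, and case panels drawn from a TFR-linked catalytic force
  of infection with a passive-immunity switch below 6 months of age.

The real nationwide KD surveillance data are not publicly deposited;
every estimator here is validated by parameter recovery on synthetic
panels whose generating mechanism embodies the same models the analysis
assumes. See the methods vignette
(`vignettes/kd-surveillance-methods.Rmd`) for the models, defaults, and
their rationale.

## Worked example

The `analysis/` directory holds the end-to-end workflow as numbered
drivers (simulate → metrics → cross-section → time series →
reconstruction), writing their tables under `results/`. Running them in
order prints, among other things:

```
$ Rscript analysis/01_simulate.R
regions: 47, case years: 1979-2010, total cases: 190699
national TFR declines 2.04 -> 1.23

$ Rscript analysis/02_metrics.R
incidence (per 100,000 0-4y): median 133.8, IQR 116.3-154.3
crude mean age: 1.86-5.10 y; the two incidence measures rank-correlate at 0.996

$ Rscript analysis/04_time_series.R
Box-Cox theta for annual incidence: -0.46
univariate optima:
  ...
  TFR                  G= 2 W=2  beta=  -0.083  R2=0.764
multivariate retains: temperature, TFR  (overall R2 = 0.770, n = 376)

$ Rscript analysis/05_reconstruct.R
univariate TFR model: G=2 W=2 beta=-0.083 theta=-0.46
reconstructed 42 years (1969-2010); in-sample correlation with the national mean: 0.995
```

Reading the output: the grid search singles out TFR as the dominant
covariate of normalized incidence with a negative coefficient — higher
fertility, lower incidence — at a lag consistent with the 5-year TFR
window that drives the generator's hazard; the multivariate model keeps
TFR after elimination; and the reconstruction, which uses only the fixed
part of the fitted model and the national TFR series, tracks the
generated national incidence trajectory at correlation 0.995 while (by
construction) smoothing over year-to-year fluctuations.

The same machinery is exposed as ordinary functions:

```r
library(kdpanel)
sc   <- scenario_config(seed = 1)
covs <- simulate_covariates(sc)
lp   <- simulate_linear_panel(sc, covs)        # truth: beta = -6, phi = 0.5, (G*, W*) = (15, 2)
tfr  <- subset(covs$covariates, variable == "TFR")[, c("region", "year", "value")]
gs   <- grid_search_lag(lp$panel, tfr)
gs$spec                                        # $G 15, $W 2
gs$fit$coefficients$estimate                   # -6.73
```

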