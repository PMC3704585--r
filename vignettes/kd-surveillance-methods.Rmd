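---
title: "Methods: spatio-temporal ecological regression of Kawasaki disease surveillance panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spatio-temporal ecological regression of Kawasaki disease surveillance panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kdpanel)
```

## The scientific problem

Kawasaki disease (KD) is an acute paediatric vasculitis of unknown
aetiology, widely believed to involve an infectious trigger. Its incidence
in Japan has risen steadily since the condition was first described, and
both incidence and the mean age of patients vary across prefectures. If a
ubiquitous agent causes KD, the mean age at onset is informative in a way
incidence is not: under a catalytic model with constant force of infection
$\lambda$ (the per-year hazard that a susceptible child contracts the
agent), ages at first infection are exponential and the mean age is

$$A \approx 1/\lambda,$$

so mean patient age is an *inverse surrogate* of the hazard. The package
implements an ecological regression workflow that links prefecture-level
KD incidence and mean patient age to climatic and socioeconomic
covariates — above all the total fertility rate (TFR), whose decline is
hypothesized to have reduced sibling-driven transmission — across space
(cross-sectional and spatial-lag regressions on period-pooled values) and
time (distributed-lag panel regressions), and reconstructs the national
incidence trajectory backwards in time from the fitted TFR model.

Because the underlying nationwide surveillance data are not publicly
deposited, the package ships a synthetic-panel generator with known ground
truth; every estimator is validated by parameter recovery on panels whose
generating mechanism embodies the same model the analysis assumes.

## Surveillance metrics

Cases are stratified into 19 fine age classes (3-month classes below age
2, 6-month classes to age 4, 1-year classes to age 10, and an open
$\geq 10$ y class). Census population resolves single years of age, so
demographic adjustment works on an 11-class aggregation (`<1y`, ten
1-year classes, open class). Midpoints are computed in years from the
month bounds, $(\ell_k + u_k)/2/12$; the open class has no natural
midpoint and defaults to 10.5 y (15 y is offered as a sensitivity value —
a class that rarely holds cases, so the choice is immaterial in
practice, which is exactly what the sensitivity variant demonstrates).

* **Incidence** is all-ages case counts per 100,000 population aged 0–4
  years — the conventional KD denominator, since cases concentrate there.
* **Age-standardized incidence** uses the direct method,
  $10^5\sum_k (N_k/P_k)\,S_k$, against a fixed standard structure
  (year-2000 national population in the intended application).
* **Crude mean age** is the case-weighted mean of class midpoints.
* **Adjusted mean age** reweights class counts by $S_k/C_{ijk}$ — the
  ratio of standard to local population share in class $k$ — before
  averaging, removing the artifact that a prefecture with relatively many
  infants records a younger mean age for purely demographic reasons. When
  the local structure equals the standard it reduces to the crude mean
  age, an identity asserted in the tests.
* Region-years with zero cases yield *missing* metric values, never
  zeros: a mean age of zero is meaningless, and regressions use complete
  cases.

Pooled variants (counts summed over the study period per region,
population structure averaged over the period) serve the cross-sectional
analyses, damping year-to-year epidemic fluctuations.

## Normalization

Dependent variables are skewed, so each analysis normalizes its response
by the Box-Cox transform $y' = (y^\theta - 1)/\theta$ ($\ln y$ at
$\theta = 0$), with $\theta$ estimated by maximizing the normal profile
log-likelihood including the Jacobian term $(\theta - 1)\sum\ln y$. The
search runs a coarse 81-point grid over $[-5, 15]$ refined by
golden-section optimization; the wide default interval matters because
narrowly dispersed, left-skewed variables (a pooled mean age varying over
a fraction of a year) can need powers near 10. $\theta$ is fitted per
dependent variable and per analysis on exactly the sample entering that
regression, and recorded in the run manifest. At $n$ in the hundreds the
estimate carries sampling error of a few tenths; the recovery tests
therefore check Monte-Carlo means, not single draws. The exact inverse
transform is used for reconstruction; predictions that leave the
invertible range ($\theta y' + 1 \le 0$, possible in deep backcasts) are
clamped to a configured floor (default 0) with the event logged.

## Cross-sectional and spatial regression

Pooled normalized metrics are regressed on period-mean covariates by
ordinary least squares, then covariates with $p \ge 0.05$ are removed by
backward stepwise elimination — one variable per step, largest p-value
first, which makes the procedure deterministic and column-order
invariant.

Prefectural outcomes are not independent samples: neighbours resemble
each other. The spatial-lag model
$$Y = \rho U Y + X\beta + \varepsilon$$
absorbs that autocorrelation through a binary adjacency matrix $U$
(1 when two regions share a border or a bridge/tunnel connection). $U$ is
deliberately left *unstandardized* — its elements are defined as 0/1 —
so the admissible interval for $\rho$ is $(1/\omega_{\min},
1/\omega_{\max})$ in terms of the extreme eigenvalues of $U$ itself.
Estimation maximizes the likelihood concentrated over $\rho$, with the
log-Jacobian $\ln|I - \rho U| = \sum_i \ln(1 - \rho\,\omega_i)$ computed
from the (symmetric) eigendecomposition. Standard errors come from the
observed information of the full likelihood via a central-difference
Hessian in $(\beta, \rho, \ln\sigma^2)$, and p-values are two-sided
normal — standard ML practice; a likelihood-ratio variant would be
equally defensible but Wald statistics keep the elimination loop cheap.
The reported $R^2$ is the squared correlation of reduced-form fitted
values $(I - \rho U)^{-1}X\beta$ with the observations. Fixing $\rho = 0$
reproduces OLS exactly, which the tests assert to $10^{-6}$.

## Distributed lags and the panel model

Covariates may act with delay: the children whose KD risk is measured in
2010 were born into the fertility environment of years earlier. The lag
transform replaces a covariate at dependent year $j$ by its mean over the
closed window $[j-G-W,\; j-G+W]$ — lag $G$, smoothing radius $W$ — so
dependent year 2010 with $G=20$, $W=5$ averages 1985 through 1995.
Windows reaching before the covariate record yield missing values and the
regressions use complete cases; that is also why multivariate sample
sizes shrink relative to the full panel. A biennially recorded covariate
(physician density) is first interpolated to annual resolution, filling
single-year gaps with the flanking mean and never extrapolating.

The panel model is
$$Y_{ij} = \alpha + X_{ij}\beta + \nu_i + \varepsilon_{ij},\qquad
  \varepsilon_{ij} = \phi\,\varepsilon_{i,j-1} + \eta_{ij},$$
with a region random effect $\nu_i$ and a single AR(1) coefficient
$\phi$ pooled across regions. Estimation is two-step feasible GLS,
chosen over full ML because it is deterministic, dependency-light, and
validated here by parameter recovery:

1. a within-region (demeaned) first pass gives residuals free of
   $\nu_i$;
2. $\phi$ is the pooled lag-1 autocorrelation of those residuals over
   consecutive-year pairs, corrected for the $O(1/T)$ downward bias of
   mean-removed AR(1) estimates by the Marriott–Pope inversion
   $\hat\phi = (T\hat\phi_{\text{raw}} + 1)/(T - 3)$ — at $T \approx 11$
   the raw estimate of a true $\phi = 0.5$ centres near $0.27$, so the
   correction is not optional;
3. Prais–Winsten quasi-differencing within each region's runs of
   consecutive years (first observation of a run scaled by
   $\sqrt{1-\phi^2}$);
4. Swamy–Arora random-effects GLS on the transformed data, quasi-demeaning
   each region by its own shrinkage factor
   $1 - \sqrt{\sigma^2_\eta/(T_i\sigma^2_\nu + \sigma^2_\eta)}$.

Regions with fewer than three consecutive usable years are dropped with a
warning. The **overall $R^2$** is defined as the squared correlation of
the fixed part $\hat\alpha + X\hat\beta$ with the observations — the
conventional "overall" statistic for random-effects panels.

For each dependent–covariate pair, `grid_search_lag()` fits the model at
every $(G, W)$ in $[0, 30]\times[1, 5]$ (configurable; the window-mean
computation is shared through cumulative sums so the 155-cell grid costs
well under a second) and selects the cell with the largest overall $R^2$,
with ties broken by smallest $G$ then smallest $W$. $W = 0$ is excluded
from selection: unsmoothed point lags make the $R^2$-vs-$G$ profile
unstable. Multivariate models then hold every covariate at its
univariate-optimal spec — specs are fixed before multivariate modelling —
and apply the same backward elimination as the cross-sectional stage.

## Reconstruction

The univariate TFR model is transferred from the regional panel to the
national TFR series — a deliberate model-transfer step recorded in the
output provenance. Each target year gets the normalized prediction
$\hat\alpha + \hat\beta\,\bar{x}_{[j-G-W,\,j-G+W]}$, inverted through the
Box-Cox fit; only the fixed part enters, so the curve captures the
secular trend and by construction cannot reproduce epidemic-year spikes.
Run backwards in time this is a retrograde extrapolation; target years
whose window precedes the series start are reported missing rather than
padded, and inverse-transform underflows clamp at zero with the events
counted in the provenance block, which suffices to reproduce the output
bit-for-bit.

## The synthetic scenario

Two generators share one configuration (`scenario_config()`, seed
mandatory; every output is reproducible from the config alone):

* `simulate_covariates()` lays the regions out on a near-square lattice
  and draws each covariate as a spatially autocorrelated field
  (simultaneous autoregression on the row-standardized lattice, default
  autocorrelation 0.5) plus a deterministic trend and annual noise. TFR
  declines linearly in expectation from 2.1 to 1.3 across 1965–2010 with
  regional spread 0.15 and year noise 0.12 — the scale of Japan's
  post-1965 fertility record. Physician density is emitted biennially to
  exercise interpolation.
* `simulate_linear_panel()` generates the response from the panel model
  itself at an embedded lag spec, default $\alpha = 10$,
  $\beta_{\text{TFR}} = -6$ (the magnitude of the multivariate TFR
  coefficient on a normalized-incidence scale), $\phi = 0.5$,
  $\sigma_\nu = \sigma_\eta = 0.3$, $(G^*, W^*) = (15, 2)$. This is the
  validation bed: recovery of $\beta$, $\phi$ and $(G^*, W^*)$ is the
  package's core acceptance property.
* `simulate_catalytic_cases()` is mechanistic: each region-year's hazard
  is $\lambda_{ij} = a + b\,\overline{\text{TFR}}$ (defaults
  $a = 0.05$, $b = 0.25$ on a 5-year window, giving $\lambda \approx
  0.4$–$0.6$/y and mean ages near 2 y, the observed KD scale), ages at
  first infection are exponential, infections below 6 months are
  suppressed with probability 0.8 (a passive-immunity switch — KD is
  rare in early infancy; tests that check the $A = 1/\lambda$ identity
  turn it off), and surviving events are binned into the fine scheme
  with Poisson event counts around 150 cases per region-year. The
  population pyramid is built from the TFR trajectory itself (cohort
  sizes proportional to lagged TFR around a 20,000-birth base), so
  crude and adjusted mean ages genuinely differ across regions. The
  positive default link slope encodes the sibling-transmission
  interpretation: more children per family, higher hazard — and
  produces, end to end, the negative TFR–mean-age correlation that is
  the analysis's central qualitative finding.

What the generator does *not* emulate: reporting-rate variation,
epidemic years, seasonality, diagnostic-criteria revisions, and any
mechanistic maternal-antibody dynamics beyond the cutoff switch. Passing
recovery tests therefore demonstrate estimator correctness under the
model's own assumptions, not robustness of the epidemiological
conclusion to real-data pathologies.

## Numerical choices and degenerate inputs

* Problem sizes in the tests: 47 regions × 11 years for panel recovery
  (200 replicates), 100 replicates for lag-spec selection, 200
  replicates at $n = 47$ for spatial recovery, 50 replicates at
  $n = 500$ for the Box-Cox power — sizes matched to the study design
  the package targets.
* $\hat\phi$ is clamped to $[-0.98, 0.98]$ after bias correction; a raw
  estimate at or beyond $\pm 1$ is an error.
* $\hat\rho$ at the boundary of its admissible interval warns; a
  supplied $\rho$ outside it errors.
* Backward elimination returning an empty model yields a flagged
  intercept-only fit rather than an error.
* Zero-variance vectors give an overall $R^2$ of 0 by convention.
* Constant samples make the Box-Cox likelihood flat and are rejected.
* All calendar arithmetic is in whole years with closed windows.

## Limitations

The estimator equivalences are asserted at the level of parameter
recovery, not against a specific proprietary implementation; the FGLS
panel estimator is consistent but not efficient relative to full ML, and
its reported variance components live on the quasi-differenced scale.
Cross-sectional spatial p-values are Wald-based. With 47 regions an
ecological regression cannot exclude confounding — the package
reproduces a hypothesis-generating analysis, and its synthetic validation
shows the machinery recovers truth when the model is true, nothing
stronger.
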