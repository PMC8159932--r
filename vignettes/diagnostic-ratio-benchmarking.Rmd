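---
title: "Passive-sampling inference and HCB/PeCB diagnostic-ratio benchmarking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Passive-sampling inference and HCB/PeCB diagnostic-ratio benchmarking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(srbench)
```

## The model

Silicone rubber (SR) absorbs hydrophobic organic contaminants (HOCs) from
water in proportion to their fugacity. Exchange between water and polymer
is first-order and, for most HOCs on SR, controlled by the water boundary
layer. Three equations carry the whole inference:

* **PRC retention.** A performance reference compound spiked into the
  polymer dissipates during exposure as
  $f = N_t/N_0 = \exp(-R_s t / (m K_{sw}))$, where $t$ is the exposure
  time (d), $m$ the sampler mass (kg) and $K_{sw}$ the polymer–water
  partition coefficient (L/kg).
* **Sampling-rate model.** Under boundary-layer control the sampling rate
  scales weakly with hydrophobicity, $R_s = \beta_{sil} K_{sw}^{-0.08}$,
  with a single exposure-specific transfer factor $\beta_{sil}$
  (L$^{1.08}$ kg$^{0.08}$ d$^{-1}$) shared by all compounds of a
  deployment.
* **Uptake model.** The freely dissolved concentration follows from the
  accumulated mass by
  $C_w = n_{acc} / \left(K_{sw} m (1 - e^{-R_s t/(K_{sw} m)})\right)$,
  valid across the linear, transitional and equilibrium regimes. The
  degree of equilibrium $DEQ = 1 - e^{-R_s t/(K_{sw} m)}$ locates a
  measurement on that continuum.

$\beta_{sil}$ is estimated by nonlinear least squares on the observed PRC
fractions of a panel spanning several log units of $K_{sw}$. Because the
model is monotone in a single parameter, we minimise the residual sum of
squares over $\log_{10}\beta$ on the fixed bracket $[-3, 6]$ with
deterministic bounded one-dimensional search (tolerance $10^{-10}$):
convergence does not depend on a starting value and repeated fits are
bit-identical. The reported standard error is the asymptotic Gauss–Newton
approximation. Unweighted least squares on fractions is the default; a
variance-stabilising $1/(f(1-f))$ weighting is available behind an option
but off, to keep the canonical form of the method.

Degenerate panels are flagged rather than fitted: all fractions at or
above 0.99 mean the data cannot see $\beta$ from below
(`uninformative_lower`, $\beta = 0$), and all fractions below $10^{-6}$
mean it is unbounded from above (`uninformative_upper`). The $10^{-6}$
threshold is deliberately strict — a fraction of a few per mille still
carries real information about $\beta$. Observed fractions above 1
(analytical noise) are clipped to 1 for fitting and kept raw for audit;
PRCs below the limit of quantification (LOQ) enter with $f = 0$ by
default because the continuous-$f$ least-squares formulation is defined
there, with an option to exclude them instead.

## Henry's-law scaling and the diagnostic ratio

HCB and PeCB are banned, persistent, and volatile enough that their air
and surface-water concentrations approach phase equilibrium at regional
scale. At equilibrium the water-phase concentration ratio of the pair is
the air-phase ratio times $H_{PeCB}/H_{HCB}$. Henry constants are carried
as dimensionless values at 20 °C (0.015 for HCB, 0.014 for PeCB) and
extrapolated in temperature with van 't Hoff slopes
$d\ln H/d(1/T)$ of 6000 K and 5200 K:
$H(T) = H_{ref}\exp\!\big(s\,(1/T - 1/T_{ref})\big)$.

The slopes are applied with a literal positive sign. This is a deliberate
choice: with these constants it reproduces the pair's published ratio
endpoints (0.76 at 0 °C, 1.02 at 30 °C), whereas the thermodynamically
conventional reading of a positive $d\ln H/d(1/T)$ would make $H$ fall
with rising temperature and invert the seasonal pattern. Because slope
tables in the literature differ in convention, a
`sign_convention = "thermodynamic"` switch flips the sign. No salinity
correction is applied to $H$ or $K_{sw}$ anywhere in the package.

Mass-basis and molar-basis ratios scale identically through this mapping
(the molecular-weight factors cancel between phases); the MW ratio of the
pair, 284.8/250.3 ≈ 1.14, is exposed separately for reporting.

## Outlier limits and classification

Background ratios are screened with three interchangeable constructions:

* **IQR with inversion** (`iqr_outlier_limits()`): upper limit
  $Q_3 + 1.5\,IQR$. Subtracting on the lower side can go negative for a
  positive ratio, so the lower limit is built on the inverted ratios —
  the upper limit of $1/r$ computed the same way and back-transformed.
  Quartiles use linear interpolation (R's type 7), recorded in the
  provenance so limits are bit-reproducible. The construction is
  scale-equivariant. For a lognormal background with $\sigma_{\log} = 0.3$
  the band holds about 95.7% of the mass (the closed form puts both edges
  at $z \approx 2.0$); for near-normal ratios the upper tail beyond the
  limit is ~0.3% and overall coverage settles near 98%.
* **Normal band** (`normal_band_limits()`): median $\pm k\sigma$ with
  $\sigma = IQR/1.35$ and $k = 3$ by default, appropriate for the tight,
  symmetric marine ratio distribution.
* **Fixed bands** (`default_ratio_limits()`, `fixed_limits()`): the
  published freshwater band (2.2, 7.0) — air limits (2.4, 7.9) scaled by
  the Henry ratio at 15 °C — and the marine band (2.44, 3.08). These are
  inputs, not recomputed quantities: the air-side quartiles behind them
  are not part of any shipped dataset.

Classification is a partition: ratio above the upper limit →
`hcb_elevated`, below the lower → `pecb_elevated`, else `background`;
censored records are `indeterminate`. Regime cut-offs for the uptake
model (DEQ 0.05 and 0.95 for linear / near-equilibrium) are module
defaults with no published counterpart, and configurable.

## Benchmarking

Other HOCs are benchmarked by expressing their $C_w$ relative to HCB and
PeCB per deployment, taking site medians, ranking sites by descending
ratio and reporting the max/min span. When a deployment lacks usable
$C_w$ but has masses and *all* involved compounds sampled in the linear
regime (DEQ < 0.05), the accumulated-mass ratio stands in — under linear
uptake it equals the concentration ratio up to the factor
$(K_{sw,b}/K_{sw,a})^{0.08}$, which the package reports explicitly
(`linear_ratio()`). Outside the linear regime concentration-based ratios
are mandatory; the pipeline prefers them whenever PRC data exist.

The network-wide ratio is estimated as the through-origin least-squares
slope of $C_w(HCB)$ on $C_w(PeCB)$ (via `stats::lm`), with a
free-intercept variant available. Note a structural property of this
estimator: multiplicative noise on the regressor attenuates the slope by
roughly $1/(1+cv^2)$ (≈ 3% at 17.5% noise), so recovered slopes sit
slightly below the generating ratio. No correction is applied — this is
the estimator practitioners fit to field data, and field estimates carry
the same property.

## Phase partitioning

The diagnostic assumes the freely dissolved phase dominates. The
three-phase check
$f_{diss} = 1/(1 + K_{DOC}[DOC] + K_{OC} f_{OC} [SPM])$
(`dissolved_fraction()`) quantifies that: with $\log K_{DOC} = 4.4$ for
HCB, a few mg/L of DOC binds < 10% of the total, and the bound fraction
reaches 50% only near $1/K_{DOC} \approx 40$ mg/L of organic carbon —
tens of mg/L. Plankton sorption is folded into the SPM term, and $K_{OC}$
defaults to $K_{DOC}$ (with a warning) when unspecified, since a
measured SPM coefficient is rarely available.

## The synthetic-data generator

`generate_scenario()` emulates a multi-site SR campaign:

* True $C_w(PeCB)$ per site is lognormal; the default spread
  (`cw_sdlog = 0.55`) puts the central 95% of site levels within about an
  order of magnitude, matching the span seen across European background
  networks. `cw_sdlog = 0` gives the single-mean variant in which
  concentrations only fluctuate around a common level — the framing used
  for ratio-recovery checks.
* $C_w(HCB)$ is the background ratio (freshwater 4.1, marine 2.76) times
  $C_w(PeCB)$; each compound's value is then perturbed independently by a
  mean-one multiplicative lognormal factor with CV `cv_noise` (default
  0.175, the middle of the 15–20% band). Two independent noisy factors
  compound, so recovered ratios show CVs around 0.25.
* Contamination injections multiply a named compound's true $C_w$ at a
  named site and are recorded as truth labels for
  sensitivity/specificity checks.
* The per-deployment $\beta_{sil}$ is drawn log-uniform over `beta_range`
  (default 2–120), spanning sampling rates from below 1 L/d (winter) to
  about 50 L/d (summer) for a log $K_{sw}$ 4.5 compound.
* PRC fractions and analyte masses are forward-simulated through the
  retention and uptake models, each with multiplicative measurement noise
  of RSD `measurement_cv` (default 11.5%, a typical inter-batch
  analytical figure); masses below `loq_ng` are flagged censored.
* The seasonal air-ratio series interpolates winter (3.98) and summer
  (5.30) medians with a log-space sinusoid whose minimum is pinned to
  mid-January, plus lognormal noise.

What the generator does **not** emulate: hydrology (flow, mixing,
dilution), spatial correlation between sites, fouling, temperature- or
salinity-dependence of $K_{sw}$, degradation, or seasonal covariance
between $\beta$ and concentration. Passing tests on synthetic data
therefore demonstrate the correctness and statistical behaviour of the
inference chain, not the field performance of the sampler.

## Numerical choices and problem sizes

* The uptake model switches to its series limit $n_{acc}/(R_s t)$ when
  $R_s t/(K_{sw} m) < 10^{-12}$, avoiding 0/0.
* Censored values propagate as flags, never as zeros; ratio operations
  drop pairs with a censored member and count them.
* All randomness flows through a single integer seed per scenario;
  identical configurations produce identical datasets, and the
  deterministic optimiser makes whole-pipeline re-runs bit-identical.
* Test and validation problem sizes — 48-site networks, 200-replicate
  noise studies, $10^4$–$10^5$-draw limit-coverage checks — were chosen
  as the smallest sizes at which the statistical assertions are stable;
  the full suite runs in seconds.

## Known limitations

* The asymptotic SE on $\beta_{sil}$ understates uncertainty for small
  PRC panels; no bootstrap is provided.
* Uncertainty is not propagated from $\beta$ to $C_w$.
* The fixed marine band (2.44, 3.08) is shipped as printed; the exact
  dispersion estimate behind it is not reconstructable, so
  `normal_band_limits()` parameterises the construction without claiming
  to reproduce that band from data.
* Through-origin slope attenuation under noisy regressors (above) is
  inherent to the estimator, not corrected.
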