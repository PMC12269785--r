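---
title: "Space-time quantile forests for soil organic carbon density: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Space-time quantile forests for soil organic carbon density: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(socforest)
```

## Scope

`socforest` implements, at desk scale, a 3D+T (two horizontal dimensions,
depth, and time) framework for mapping soil organic carbon density
(SOCD, kg organic carbon per m^3 of soil) with per-pixel uncertainty:
harmonization of heterogeneous laboratory records into SOCD, a joint
mean + quantile random forest with spacetime-block aggregation, recursive
feature selection by cumulative importance, validation of predictions and
prediction intervals, isolation-forest extrapolation risk, and the
propagation of pixel-level uncertainty to regional aggregates through a
variogram of standardized residuals. A synthetic landscape generator with
known ground truth makes every stage testable without external data.

## Harmonization

Laboratory records report SOC content (g/kg), bulk density (BD, g/cm^3)
and coarse fragments (CF, % > 2 mm). Two derivations are supported,
depending on which BD/CF variant a survey provides:

* total bulk density with mass-based fragments:
  `SOCD = SOC * BD_tot * (1 - 0.01 * CF_mass)`;
* fine-earth bulk density with volume-based fragments:
  `SOCD = SOC * BD_fe * (1 - 0.01 * CF_vol)`.

With these units the product is directly kg/m^3. SOC measured by
Walkley-Black is converted to dry-combustion equivalents with the widely
used factor 1.3; Springer & Klee is treated as dry-combustion-compatible
(factor 1.0), a choice we make explicit because surveys list the method
without a stated factor. Loss-on-ignition and method-less records are
rejected outright: published LOI conversion factors vary several-fold, so
any single factor would inject bias. Depth becomes the midpoint of the
recorded limits (or the single recorded value); records lacking year,
coordinates, depth or a complete SOC/BD/CF triplet are rejected with
machine-readable reason codes. Zero-SOCD records are excluded unless the
land cover is a bare class, while *pseudo-zero* surface points (2.5 cm
depth, configurable up to 5 cm) are deliberately placed on bare rock and
shifting sand so the model learns the covariate signature of non-soil
environments; they participate in training only and never in metrics or
test sets.

SOCD is strongly right-skewed, so all modelling happens on the `log1p`
scale with `expm1` back-transformation of means and quantiles. The mean
is back-transformed directly without a lognormal smearing correction —
the forest estimates the conditional mean of the transformed response,
and quantiles are monotone-invariant, so the interval bounds are exact
either way.

## The joint mean + quantile forest

Trees are grown by `ranger`; the package retains, per tree, the multiset
of in-bag training responses in every terminal leaf (reconstructed from
the stored in-bag counts and terminal-node assignments, with bootstrap
multiplicity). One fitted object then yields:

* the **mean** — the average over trees of leaf means, identical to the
  standard forest prediction;
* **leaf-pooled quantiles** (default at point support) — empirical
  quantiles of the union of all trees' leaf multisets, the quantile
  regression forest estimator;
* **tree-ensemble quantiles** — quantiles of the per-tree mean
  predictions, used for spacetime blocks.

The two quantile modes deliberately coexist: pooled leaf distributions
describe the conditional distribution of a single observation, which is
what a point-support 95% interval should cover; the spread of per-tree
means describes ensemble uncertainty of an averaged quantity, which is
the right object once predictions are averaged over block nodes.

A **spacetime block** is a set of N (year, depth) nodes — typically the
four corners of a year-interval x depth-interval cell. For each tree the
node predictions are averaged first; the block mean and interval come
from the distribution of these per-tree block values. When node errors
are independent (e.g. inter-annual noise in dynamic covariates), the
ensemble spread shrinks by about `1/sqrt(N)`; the test suite verifies the
x0.5 reduction at N = 4 on a scenario built to have independent years.

Ensemble size is fixed at 120 trees throughout: forests saturate well
before that for these problem sizes, and a fixed count keeps leaf
storage predictable. The tuning space mirrors the published forest search
space expressed in the tree engine's own terms — split rule
{variance, extratrees}, `max_depth` {10, 20, 30}, feature fraction
{0.3, 0.5, 0.7, log2, sqrt}, minimum leaf size {1, 2, 4} — searched by
successive halving (factor 3) on growing training fractions and settled
by 5-fold cross-validated CCC.

## Feature selection (RSCFI)

Repeated-subsampling cumulative feature importance: at each iteration,
default forests are fitted on five random half-subsamples, their
normalized impurity importances averaged, features sorted, and only the
smallest descending-importance prefix whose cumulative mass reaches a
threshold is kept. Iterations stop when nothing is dropped or two
features remain; the returned set is the iteration with the best
cross-validated CCC, with folds held fixed across iterations so the
comparison is paired.

The threshold is a *mass* threshold and therefore scales with pool size:
0.99 is appropriate for pools of hundreds of features where irrelevant
features hold a fraction of a percent each; for the 25-feature benchmark
pool used in the tests each noise feature holds roughly 2% of the mass,
so the analogous cut is 0.90. With that setting the suite demonstrates
recovery of at least 4 of 5 informative features with at most 4 noise
features retained, across five seeds.

## Validation

Point metrics — R^2, Lin's concordance correlation coefficient
(`ccc = 2*cov / (var_x + var_y + (mean_x - mean_y)^2)`, population
moments), MAE, MedAE and bias (`mean(pred - obs)`, so underestimation is
negative) — are computed on the back-transformed kg/m^3 scale, optionally
weighted. Three schemes are provided: 5-fold cross-validation with
inverse sampling-intensity weights (intensity = point count in a 25 km
grid cell, weights normalized to mean 1 — a deterministic surrogate for
kernel-based intensity estimators), leave-one-year-out cross-validation
for temporal transferability, and an independent stratified test set.
Pseudo-zeros train but are excluded from every metric. Stratified reports
(land cover x depth interval) suppress metrics for strata under five
observations.

Interval quality uses PICP (fraction of observations inside their
intervals, closed bounds), PIW (mean width), QCP per bound (fraction of
observations at or below a predicted quantile, ideally the nominal
probability — asymmetry reveals lopsided intervals), and accuracy curves
over nominal levels {0.05, ..., 0.95, 0.99}. All interval estimators are
oracle-tested against explicit counting.

Shapley attributions on the log1p scale come from a permutation-sampling
estimator against a background sample, with exact subset enumeration as
the small-case oracle (at most 10 features); both satisfy the efficiency
identity (contributions sum to prediction minus baseline) by
construction of the telescoping sums.

## Extrapolation risk

A standard isolation forest (100 trees, subsample psi = 256, height
ceiling `ceil(log2(psi))`, c-adjusted truncated leaves) scores queries by
`s = 2^(-E[h]/c(psi))`, already a normalized 0-1 scale; no additional
min-max rescaling is applied, which is the simplest mapping consistent
with a "0 to 1 extrapolation-risk probability". The classification
threshold is the dataset-average path length pushed through the same
transform; it is data-dependent and user-overridable. The two-cluster
benchmark requires AUROC > 0.9 for separating out-of-domain queries.

## Aggregate uncertainty (change of support)

Pixel error sd is approximated by `sigma = PIW / 4` (normal reading of a
95% interval). Residuals standardized by this proxy should have a
unit-sill variogram; because the proxy is approximate, the square root of
the initially fitted sill multiplies `sigma` and the residuals are
re-standardized. The variogram is Matheron's estimator on binned pairs,
fitted by weighted least squares (pair-count weights) for an exponential
(default) or spherical model. The error correlation is
`rho(h) = (sill - gamma(h)) / sill`, clipped to [0, 1].

The model-based sd of an AOI mean discretizes the AOI on a coarse grid
(default 500 m), draws one random point per cell, and evaluates

```
sd_MB = sqrt( (1/|B|^2) * sum_s sum_u sigma(s) sigma(u) rho(|s-u|) )
```

The closed-form limits anchor the implementation: `sd_MB = sigma` for a
single point or full correlation, `sigma/sqrt(|B|)` for independent
errors, monotone growth with the variogram range, and exact agreement
with a brute-force double loop. The design-based comparator is the
classical standard error `sqrt(sum (y_i - mean)^2 / (n(n-1)))`.

### Numerical choices

* `rho(0) = 1` even with a nonzero nugget: the nugget is read as
  measurement-scale noise that does not belong to the point-to-point
  error correlation, and the diagonal of the double sum must carry the
  full `sigma(s)^2`. This is an explicit modelling choice where the
  formulation is silent.
* The variogram fit optimizes log-transformed nugget and partial sill and
  a range bounded (logistically) by twice the maximum lag: a flat
  variogram otherwise makes the (partial sill, range) pair unidentifiable
  and the sill diverges. Nelder-Mead with restarts is used; bounded
  quasi-Newton proved fragile on flat plateaus.
* Quantiles of pooled leaf multisets use the standard type-7 empirical
  quantile; tests verify equality with a hand-rolled sorted-vector
  interpolation.
* Monte-Carlo discretization of the AOI is seeded; with the smooth error
  surfaces produced by interval widths, independent seeds agree on
  `sd_MB` within 5%.

## The synthetic landscape

The generator emulates the statistical structure the analysis assumes:

* **covariates** as Gaussian random fields with exponential covariance
  (circulant-embedding FFT synthesis, negative embedding eigenvalues
  clipped), standardized per layer; dynamic layers evolve as AR(1) across
  years (persistence 0.8 by default, 0 for the independence benchmark);
* **land-cover strata** (cropland / grassland / woodland and a 3% bare
  mask) from quantile-classified hidden fields, with additive mean shifts
  (grassland +0.25, woodland +0.45 on the log1p scale) and bare surfaces
  forced to ~0 SOCD;
* **latent SOCD**: `log1p(SOCD) = 2.9 + sum_j beta_j f_j + lc - 0.015 * depth`,
  truncated at zero; five informative features with magnitudes
  `0.45 * 0.85^(j-1)` and alternating signs;
* **sampling**: a mixture of uniform and parent-offspring clustered
  locations (40% clustered, 2 km spread), surface-weighted depths
  (exponential, mean 25 cm, truncated at 200 cm), and observation noise
  on the log1p scale with sd `0.30 + 0.03 * log1p(SOCD_true)`
  (heteroscedastic by default).

These defaults were chosen once to reproduce the accuracy regime reported
for continental SOCD mapping — held-out R^2 near 0.5-0.6, CCC near
0.6-0.7, 95%-interval coverage in the mid-90s, mean SOCD around
20-25 kg/m^3 with a long right tail — while keeping magnitudes physically
plausible. What the generator does *not* emulate: real covariate
semantics (climate, terrain, spectra), measurement-method mixtures across
surveys, temporal drift in sampling design, and spatially structured
*residual* error beyond what heteroscedastic noise induces. Passing tests
therefore demonstrate the correctness and internal calibration of the
machinery under a well-specified model, not performance on real soil
data.

Benchmark scenarios fix the study designs used by the test suite:
`coverage` (well-specified, heteroscedastic; interval calibration),
`selection` (5 informative among 25 features), `blocks` (dynamic-only
signal, AR(1) persistence 0; `1/sqrt(N)` checks), and `aggregate` (dense
500 m grid with an AOI polygon).

### Problem sizes

The suite and acceptance script run, per invocation: 2000/1000
train/test points on a 60 x 60 km grid for coverage checks; 1200-point
calibration sets for five seeded feature-selection runs; 500-point
clustered surveys (ten realizations, median-combined) for variogram
recovery; a 900-point end-to-end pipeline including map production over
3600 pixels and AOI aggregation on several hundred discretization
points. These sizes were chosen so each property is measured with
adequate replication while a full run remains a coffee-break affair on a
single CPU.

### Variogram-recovery design

Recovering (nugget 0.2, sill 1.0, range 5 km) from a *single* 500-point
realization is ill-posed: the range estimate alone has sampling
variability of 30-50% under any practical survey over a domain a few
ranges wide. The recovery benchmark therefore uses a clustered survey
(100 cluster centres x 5 points, 300 m within-cluster spread, 60 km
domain — tight pairs resolve the nugget, many clusters resolve the
range) and assesses the estimator by the median over ten independent
realizations, which isolates estimator bias from single-realization
noise.

## Known limitations

* Rasters are in-memory grid objects with CSV export; there is no
  GeoTIFF/COG I/O and no tiling machinery for continental mosaics.
* The lon/lat ingest projection is a spherical equal-area approximation,
  not a datum-exact transform.
* Error cross-correlation between years is not modelled, so aggregate
  uncertainties of *changes* are out of scope.
* The ISIW weighting is a deterministic grid-count surrogate; users
  needing a specific kernel intensity estimator should supply their own
  weights to `point_metrics()`.
* Tuning maps the forest criterion set onto the engine's split rules;
  `min_samples_split` has no analogue and is not searched.
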