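---
title: "Inferring altitudinal range shifts: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring altitudinal range shifts: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`oroshift` infers climate-driven altitudinal range shifts of mountain
species from two complementary sources of evidence: dated, georeferenced,
elevation-tagged occurrence records, and annual species distribution models
(SDMs) projected onto yearly climate layers. Records are direct but sparse
and unevenly sampled; model projections smooth over sampling noise but
inherit the uncertainty of climate reconstruction. The package computes the
same family of shift statistics from both, so concordant trends constitute
the strongest evidence.

This vignette explains the models and their assumptions, the parameters
that matter, what the synthetic world does and does not emulate, and the
numerical choices made where the design was genuinely open.

## The shift statistics

For a species' elevation vector $h$ (its occurrences in a year, or the
(elevation, probability) pairs of the surviving cells of a model surface),
the package computes per year the median and mean altitude, the range size,
the adjusted Fisher--Pearson skewness
$G_1 = g_1 \sqrt{n(n-1)}/(n-2)$, and the variance--mean ratio

$$\mathrm{VMR} = \frac{\sigma^2(h)}{\mu(h)},$$

an index of altitudinal range size that, unlike the raw span, is not
dominated by single extreme records. Weighted variants treat the model
probabilities as frequency weights normalized to the number of cells, so
equal weights reduce exactly to the unweighted formulas.

Per species, ordinary least-squares slopes against study year give:

* `z_alt` — altitude of every record against its year (for model series,
  the annual probability-weighted median against year);
* `z_range` — annual range size against year;
* `z_vmr` — annual VMR against year;
* `z_skew` — annual skewness against year, computed only for years with at
  least 5 sites of distinct altitude (elevations rounded to 1 m) and only
  for species with at least 5 such years, because skewness at smaller
  samples is mostly noise.

Years of the extreme records (`t_min_year`, `t_max_year`) use the single
lowest/highest occurrence with ties broken by the earliest year. Decadal
anomalies subtract each species' overall median from its within-decade
median; the per-decade community value is the median over species.

Two conventions deserve note. Record-based range size is `max - min`;
model-based range size is the weighted 5--95% quantile span, because
thresholded surfaces often retain single marginal cells whose raw extremes
are unstable. And where the weighted mean and weighted median of a surface
disagree, the median is the headline statistic (the mean is also reported):
the median is invariant under the monotone rescaling applied to the
surfaces.

## The distribution model

The SDM is a presence--background maximum-entropy model written from
scratch. Given environmental axes $x$ (PCA scores, below), features
$f(x)$ are the linear, quadratic and pairwise-product terms, each scaled to
$[0,1]$ by its background minimum and maximum. The model maximizes the
penalized log-likelihood

$$L(\lambda) = \frac{1}{m}\sum_{i \in \text{presence}} \lambda^\top f(x_i)
 \;-\; \log \sum_{j \in \text{background}} e^{\lambda^\top f(x_j)}
 \;-\; \sum_k \beta_k |\lambda_k|,
 \qquad \beta_k = \beta \, s_k / \sqrt{m},$$

with $s_k$ the presence standard deviation of feature $k$ (floored at
$10^{-4}$ so no feature is ever unpenalized) and $\beta = 1$ by default.
Optimization is full-batch proximal gradient ascent with soft-thresholding
for the L1 term, an adaptive (backtracked, re-expanding) step, an objective
tolerance of $10^{-7}$ assessed over a 20-iteration window, and a 5000
iteration cap. Only the objective is replicated from the field's standard
tool, not its sequential update schedule; tests verify that the fitted
objective value matches a generic optimizer of the same function.

The raw output $\mathrm{raw}(x) = e^{\lambda^\top f(x)}/Z$ sums to 1 over
the training background. The reported score is the cloglog transform
$1 - \exp(-e^{H}\,\mathrm{raw}(x))$ with $H$ the entropy of the fitted
distribution over the training background; a no-signal model scores
$1 - e^{-1} \approx 0.632$ everywhere.

Evaluation bootstraps 80/20 presence splits (default 100 replicates; the
pooled all-years background is not resplit), reporting training and test
AUC as the normalized Mann--Whitney statistic with ties counting one half,
and the mean 10% training omission threshold: with training scores sorted
ascending, the score at 0-based index $\lfloor 0.1\,n \rfloor$. Annual
projections are thresholded at that mean, rescaled to $[0,1]$ via
$(p - \mathrm{thr})/(p_{\max} - \mathrm{thr})$ — the grammatically
ambiguous published rule is resolved in the direction that actually yields
a $[0,1]$ range — and optionally masked by a binary land-cover grid.

## Environmental space

From monthly minimum/mean/maximum temperature and cumulative precipitation,
annual bioclimatic layers are computed with rolling 3-month quarters
(December--January wraparound). The default set is bio1--bio7 and
bio10--bio17; the hybrid wettest/warmest-quarter variables (bio8, bio9,
bio18, bio19) are excluded by default as artifact-prone, and precipitation
seasonality uses the $100\,\mathrm{sd}/(\mathrm{mean}+1)$ convention to
stay finite in arid cells. A PCA (variables z-scored, components retained
by the eigenvalue > 1 rule) trained on the conditions at the records
defines the climate axes; a second PCA on the monthly insolation layers
defines the topographic axes. Both are projected onto every year, so a
record's environment is always taken from its own year of discovery
(year-matched extraction), and background points (default 1,000 per year,
uniform without replacement within year) go through the identical path.

Coarse temperature grids are downscaled by geographically weighted
regression: per fine cell, a weighted least-squares fit of temperature on
elevation over the coarse cells with Gaussian distance weights
$\exp(-d^2/2b^2)$, default bandwidth $b$ = 3 coarse cell sizes, evaluated
at the fine cell's elevation. Fewer than 3 positive-weight neighbours give
nodata; a locally constant elevation design falls back to the weighted
mean. Precipitation, expected to correlate only weakly with elevation, is
downscaled bilinearly.

## Niche volumes

The realized niche volume is delimited by a one-class support vector
machine (RBF kernel) around the species' records in environmental space:
`nu = 0.05`, `gamma` defaulting to 1/(d x mean per-dimension variance), and
a bounding box extending one kernel bandwidth beyond the data range per
dimension. The volume is the box volume times the fraction of uniform
Monte-Carlo samples classified inside, with the binomial standard error
reported. Because the one-class boundary by construction encloses only
about $1-\nu$ of the training mass, the raw estimate is biased low by that
factor; the estimator divides by $(1-\nu)$, which makes a uniform point
cloud recover its true support volume within Monte-Carlo error. Volumes are
reported in PCA-space units and are implementation-relative: ratios and
ranks across species are meaningful, absolute values are not comparable
across tools.

## Trait models

Per-species statistics are related to ecological traits by a general linear
model: dispersal ability (sedentary/intermediate/mobile), euryocy
(specialist/generalist) and endangerment (threatened/least concern) as
treatment-coded factors (references: sedentary, specialist, threatened)
plus median altitude as a continuous covariate. Effects use Type II sums of
squares computed by single-term deletions — the standard choice for
unbalanced trait designs without interactions — with partial
$\eta^2 = SS_{\mathrm{effect}} / (SS_{\mathrm{effect}} + SS_{\mathrm{error}})$
and parametric F tests. Sums of squares below floating-point noise are
treated as exact zeros so that degenerate designs (a response identical to
a predictor) yield exact effect sizes instead of an error.

## The synthetic world

The generator produces the study conditions under which every stage is
verifiable by parameter recovery:

* a DEM spanning roughly 400--3800 m (cosine ridges plus a smoothed
  Gaussian field, optionally superimposed on a linear ramp), rescaled to
  the requested relief exactly;
* monthly climate 1961--2019 following a lapse rate of 0.0065 °C/m, a
  linear warming trend (default 0.04 °C/yr), a seasonal cycle (amplitude
  9 °C), and spatially constant per-month noise emulating interannual
  weather variability;
* monthly insolation proxies from Horn slope/aspect hillshading with a
  fixed southern azimuth;
* virtual species with Gaussian climatic niches on annual mean temperature
  and annual precipitation, Poisson record counts per year (times a
  detectability factor), uniform flight-season dates, and exact cell-centre
  coordinates.

Under warming $w$ and lapse rate $\ell$, isotherms — and with them each
species' suitability band — climb at $w/\ell$ metres per year
(0.04/0.0065 ≈ 6.2 m/yr), the programmed truth that recovery experiments
test against.

Two properties of real mountains deliberately complicate that closed form,
and both are under the generator's control:

* **Hypsometry.** The land area available per elevation band is not
  uniform on ridge-dominated terrain, and the area-weighted elevation
  distribution of a climate-tracking species is then distorted — near
  summits the available area shrinks and the apparent shift lags the
  isotherm ("mountain-top squeeze"). Hypsometric density scales with the
  local terrain gradient, so even small-amplitude ridges modulate it
  strongly. Calibration experiments therefore use `ramp_relief()`, a
  ramp-dominated relief whose hypsometry is nearly uniform and on which
  the closed-form velocity is the correct expectation; on realistic
  ridged relief the deviation is a property of the terrain, not of the
  estimators.
* **Orographic precipitation.** If precipitation rises with elevation, the
  climate PCA axes mix the (moving) temperature signal with a static
  elevation-bound signal, and the modelled distributions shift visibly
  slower than the isotherm — in experiments here a strong gradient halved
  the apparent model-based `z_alt`. The generator's `prec_elev_grad`
  therefore defaults to 0, matching the study design's assumption that
  precipitation correlates at most weakly with elevation; users can raise
  it to probe exactly this confounding.

What the synthetic world does **not** emulate: spatially structured
observation effort (detectability is a single per-species constant),
spatial autocorrelation of sampling, coordinate uncertainty, land-use
change, and microclimatic decoupling from the lapse rate. Passing recovery
tests therefore demonstrates the correctness of the estimators under the
stated generating model, not robustness to the full sampling pathology of
museum data.

## Problem sizes and determinism

Every stochastic step takes an explicit integer seed, and all stages are
deterministic given config plus seeds (the pipeline's result CSVs are
byte-identical across reruns). Tests and the bundled acceptance script use
desk-scale problems — grids of 20x20 to 100x100 cells, 20--59 years,
10--30 records per species-year, bootstrap replicate counts of 3--20,
Monte-Carlo sizes of a few thousand — chosen so the full suite completes in
minutes on a single core while keeping every statistical check comfortably
powered; all sizes scale up through the configuration without code changes.

## Known limitations

* The Maxent implementation covers linear/quadratic/product features only —
  no hinge or threshold features, no clamping or extrapolation
  diagnostics.
* GWR uses a fixed Gaussian bandwidth; adaptive bandwidths are not
  implemented.
* Absolute hypervolumes depend on `nu`, `gamma` and the box construction;
  only ratios and ranks should be interpreted.
* The record filters ("at least 13 records", "only exceptional occurrences
  below 600 m" operationalized as at most 5% of records) are configurable
  conventions, not estimates.
* Rasters are exchanged as ESRI ASCII grids (single planar coordinate
  system, no CRS handling or reprojection).
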