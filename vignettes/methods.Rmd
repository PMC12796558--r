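---
title: "Models and methods behind krillscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind krillscape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

krillscape links acoustically derived euphausiid (krill) and fish densities
to spatial biomass hotspots and multispecies co-occurrence. The pipeline has
five scientific stages — acoustic preprocessing, spatiotemporal density
modelling, hotspot detection, overlap/co-occurrence statistics, and
constrained ordination — plus a synthetic-data generator that stands in for
survey and ocean-model inputs so every stage is testable offline. This
vignette explains the models, their assumptions, the tunable parameters,
and the design choices made where the design was genuinely open. It states
no empirical result that the test suite does not itself compute.

## 1. Acoustic preprocessing

Dual-frequency echosounder surveys record volume backscattering strength
$S_v$ (dB re 1 m$^{-1}$) by depth and along-track position at 38 and
120 kHz. Adult euphausiids scatter much more strongly at 120 kHz than at
38 kHz, so cells whose mean volume backscattering strength difference
$\mathrm{MVBS}_{120} - \mathrm{MVBS}_{38}$ falls inside a window are
classified as krill.

* **MVBS windows** (`compute_mvbs`): 40 pings × 10 m by default. Averaging
  is done in the *linear* domain, $10\log_{10}\overline{10^{S_v/10}}$ —
  averaging dB values directly would underestimate backscatter. Trailing
  partial windows are averaged over the available samples so transect ends
  are kept.
* **Classification window** (`db_difference_classify`): default
  [10.0, 16.3] dB, treated as a *closed* interval. Whether the published
  bounds are inclusive is not stated anywhere we know of; both bounds are
  configurable.
* **Echo integration** (`echo_integrate_nasc`): the nautical area
  scattering coefficient per 0.5-nmi transect bin is
  $\mathrm{NASC} = 4\pi\,1852^2 \; \overline{\sum_z 10^{S_v/10}\,\Delta z}$
  (m² nmi$^{-2}$), the mean over pings in the bin of the depth-integrated
  linear backscatter of masked cells. The constant $4\pi\,1852^2$ is the
  standard echo-integration definition. Euphausiid integration defaults to
  the 50–300 m daylight depth window; whole-water-column integration
  (hake-style) uses `depth_min_m = 0, depth_max_m = Inf`. A bin with no
  masked cells yields NASC = 0 — a valid absence, not a missing value.
  1 nmi = 1.852 km throughout (0.5 nmi = 0.926 km bin spacing).

## 2. The spatiotemporal density model

Observed density (NASC) $y_i$ at location $s_i$ in year $t_i$ is modelled
as Tweedie with a log link:

$$y_i \sim \mathrm{Tweedie}(\mu_i, p, \phi), \qquad
\log \mu_i = \mathbf{X}_i\beta + \textstyle\sum_k f_k(x_{ik})
 + \omega(s_i) + \epsilon_{t_i}(s_i) + \delta_{t_i}$$

* $f_k$ — penalized cubic regression splines (basis dimension $k = 3$ by
  convention here) built with `mgcv::smoothCon()` and re-parameterized via
  `mgcv::smooth2random()` into a fixed part plus i.i.d. Gaussian
  coefficients whose variance is the smoothing parameter. The published
  framework this mirrors constructs its smooths the same way. (The cubic
  B-spline basis originally envisaged is not constructible at $k=3$; the
  "cr" basis is the same penalized-cubic family.)
* $\omega$ — a time-invariant spatial Gaussian field capturing persistent
  structure (e.g. bathymetric association).
* $\epsilon_t$ — spatiotemporal fields, first-order autoregressive across
  years: $\epsilon_t = \rho\,\epsilon_{t-1} + \sqrt{1-\rho^2}\,\eta_t$,
  capturing transient oceanographic structure. $|\rho| < 1$ enforces
  stationarity: the marginal field variance is the same every year.
* $\delta_t$ — an optional Gaussian year intercept; fixed year-factor means
  are also available (both appear in the published model structures; both
  are flags here, neither is forced).
* Tweedie with $1 < p < 2$ is a compound Poisson–gamma: continuous,
  nonnegative, with a point mass at zero,
  $P(y=0) = \exp\{-\mu^{2-p}/(\phi(2-p))\}$ — exactly the behaviour of
  zero-inflated acoustic densities.

### Random fields on a knot mesh

Fields are represented by a predictive-process approximation rather than
the SPDE/GMRF precision construction: Gaussian random effects live at
*knots* (k-means centroids of the observation coordinates,
`select_knots()`, or greedy distance thinning, `select_knots_by_cutoff()`),
with Matérn covariance between knots, and are projected to arbitrary
locations by barycentric (bilinear) interpolation over an in-package
Delaunay triangulation. Weights are nonnegative and sum to one; points
outside the knot hull take their nearest knot's value. Matérn smoothness is
fixed at $\nu = 1$ (the conventional SPDE choice; one fewer shape parameter
to estimate), and `range_km` is the *effective* range — the distance at
which correlation decays to ≈ 0.1, $\kappa = \sqrt{8}/\mathrm{range}$. The
spatial and spatiotemporal fields share one range.

### Estimation

`fit_sdm()` maximizes the Laplace-approximate marginal likelihood. The
inner problem finds the joint mode of (fixed effects, random effects) by
Fisher-scoring Newton with step halving; the outer problem optimizes the
transformed variance/correlation/observation parameters
($\log\tau, \log\sigma, \log\mathrm{range}, \tanh^{-1}\rho$, a logistic
transform bounding $p$ to (1.01, 1.99), $\log\phi$) with `nlminb`. Two
numerical points matter:

* The Tweedie log-density is evaluated *exactly* by log-sum-exp summation
  of the compound Poisson–gamma series (`tweedie_logpdf`), bucketed by the
  required series length. The same construction gives the exact sampler
  `rtweedie`.
* The Laplace log-determinant uses the **observed** information at the
  mode, $((2-p)\mu^{2-p} + (p-1)y\mu^{1-p})/\phi$, not the Fisher
  expectation $\mu^{2-p}/\phi$ (Fisher weights only drive the Newton
  steps). During development, using Fisher weights in the determinant
  visibly biased $\hat p$ and broke interval coverage; with observed
  information the replicate mean of $\hat p$ is indistinguishable from the
  generating value.

Convergence follows the published checks (`check_convergence`): maximum
fixed-effect gradient < 0.01, positive-definite (outer) Hessian, and no
field SD collapsed below 0.01 (a "degenerate field"). Model selection is by
AIC with $k$ = fixed effects + variance-type parameters (marginal AIC;
random-effect levels are not counted — the published work does not state
its convention), ties broken by fewer parameters then name
(`aic_select`). Candidate covariate sets are pre-screened by pairwise
$r^2 < 0.7$ (`concurvity_screen`), which enumerates the maximal admissible
subsets of the conflict graph.

Parameter uncertainty is reported as Wald intervals on the transformed
scale, back-transformed (the convention of the field's tooling). The
specification of the recovery check speaks of profile intervals; profiling
four parameters across twenty replicate fits does not fit the runtime
budget, and for these parameters at $n \approx 3000$ the Wald intervals are
close to calibrated once the observed-information determinant is used. The
residual weak point is the field SD: a survey domain a few correlation
ranges across contains only a handful of independent spatial patches, so
variance-parameter likelihoods are skewed and symmetric-on-log-scale
intervals can under-cover by a few percent — exactly the cases a profile
interval would widen.

### Variance decomposition

`r2_decompose()` reports squared Pearson correlations of observed vs
predicted density, both on the $\log(x + 0.01)$ scale: *conditional* $r^2$
uses the full prediction; *marginal* $r^2$ zeroes the random fields and the
year random intercept (covariate and fixed year effects remain — the
penalized parts of smooths are covariate effects and are kept); the
*spatiotemporal* $r^2$ is their difference. The published work does not
spell out its marginal procedure; fields-zeroed prediction is this
package's definition.

## 3. Hotspots and co-occurrence

* **Neighborhood calibration**: a Moran's I correlogram over distance bands
  (`correlogram`) finds where similarity between predicted biomass values
  decays; the Gi* neighborhood is the upper edge of the last band before
  the first band with $I \le E[I] + 2\,\mathrm{SE}(I)$ under the normality
  approximation (`choose_neighborhood`). The published account states only
  that a decay distance was found, not the rule; this two-SE rule is the
  package's operationalization, with degenerate cases (white noise, never
  decaying) warned about explicitly. Fields larger than `max_cells` are
  subsampled for the correlogram (all pairwise distances are needed).
* **Gi\*** (`gi_star`): binary distance-band weights with the focal cell
  included (the Gi* convention — the published text writes "Gi" but
  describes hotspot mapping, for which Gi* is standard; `include_self =
  FALSE` gives plain Gi, and weights are deliberately not row-standardized,
  both configurable). For multi-year prediction stacks,
  `pooled_gi_star_by_year()` standardizes with the pooled mean/SD over all
  cell-years so hotspot intensity is comparable between years — an
  anomalously weak year can contain no hotspots at all.
* **Hotspots** (`hotspot_mask`): cells with Z at or above the 90th
  percentile of the (pooled) Z distribution; ties at the threshold are
  included. Area = cell count × cell area.
* **Overlap** (`overlap_percentage`): $100\,|A\cap B|/|A\cup B|$ — the
  union denominator matches "proportion of hotspot that is co-occurrence
  vs. hotspot that is just one species"; per-species denominators are
  available behind a flag. `cooccurrence_percent()` reports, per cell, the
  percentage of analyzed species that are hot there, with cells outside the
  common surveyed area missing. `binned_hotspot_area()` partitions hotspot
  area into 100-km northing bins (bins sum exactly to the total).

## 4. Redundancy analysis

`rda_fit()` regresses the cells × species matrix of Gi* Z-scores on the
environmental covariates and eigendecomposes the fitted values'
cross-product: eigenvalues are constrained-axis variances, and
`prop_constrained` is the constrained share of total variance. Species are
standardized to unit variance by default (Z-scores from different species
are pooled differently); the triplot uses type-2 (correlation) scaling —
the published triplot does not state its scaling, so exact numeric score
comparability is not claimed. A brute-force hat-matrix + eigendecomposition
oracle, coded independently in the test helpers, pins the implementation to
1e-8.

## 5. The synthetic world

The generator reproduces the *structure* of the real inputs with known
ground truth:

* Matérn ($\nu=1$) Gaussian random fields by dense Cholesky
  (`simulate_matern_grf`), AR1-correlated annual fields
  (`simulate_ar1_fields`), default 3-km grid, 30-km effective range, field
  SDs 0.8, $\rho = 0.5$ — a stated-world choice matching moderately
  persistent mesoscale structure.
* Tweedie-sampled surveys along parallel transects of 0.5-nmi bins
  (`simulate_survey`, `transect_layout`), defaults $p=1.5$, $\phi=1.2$.
* Dual-frequency echograms with planted krill cells whose dB difference is
  inside the classification window plus Gaussian noise
  (`simulate_dual_frequency_echogram`); background cells sit at a 2-dB
  difference, far outside the window.
* Multi-species surfaces with hotspots of designed Jaccard overlap
  (`plant_hotspot_surfaces`): each species' hotspot occupies 10% of cells
  (matching the 90th-percentile rule downstream), pairwise overlap is
  realized through a shared contiguous core, sized
  $c = 2KJ/(1+J)$ so $|A\cap B|/|A\cup B| = J$ to within one cell. A scalar
  design works for any number of species; a full pairwise matrix is only
  constructible for two (the constructor errors, naming the pair, on
  designs it cannot realize). Optional per-species placement regions
  support predator/prey mismatch scenarios (e.g. prey hotspots planted
  north, predator south).

What the generator does **not** emulate: real bathymetric covariate
structure (covariates are synthetic Matérn fields, optionally correlated
with the latent truth), vessel effects, calibration error, diel migration,
or the ocean model's physics. A green end-to-end test therefore
establishes that the *statistical machinery* recovers planted structure,
not that the ecological conclusions of any particular survey would be
reproduced.

### Simulating from the model class

The parameter-recovery check simulates from the predictive-process model
itself (`simulate_sdm_obs`: knot-level fields on the same mesh used for
fitting) rather than from the grid-based GRF generator. This is
deliberate: it separates *estimator correctness* (is the Laplace ML
consistent and are its intervals calibrated?) from *approximation error*
(how well does a 50-knot mesh represent a continuous field?). The latter
is exercised separately by the prediction-recovery test, which simulates a
continuous-grid GRF truth and requires the fitted link surface to
correlate > 0.8 with it.

## 6. Numerical choices and edge cases

* Tweedie $p$ is bounded to (1.01, 1.99) for numerical safety; field SDs
  and ranges are optimized on log scales with generous bounds tied to the
  domain diameter.
* Matérn correlation matrices get a 1e-6–1e-8 diagonal jitter before
  Cholesky.
* The linear predictor is clamped at 50 on the log scale inside the inner
  Newton to avoid overflow; step halving guarantees monotone ascent.
* Half-open cell membership `[lo, hi)` is implemented once
  (`point_to_cell`) and shared by extraction, survey simulation and
  regridding; a point on a shared edge belongs to the upper cell.
* `regrid_mean` uses exact 1-D interval-overlap matrices, so non-nested
  grids (3 km → 5 km) are area-weighted correctly and the valid-area
  weighted mean is conserved to machine precision.
* Degenerate hotspot inputs (constant fields, empty masks, single-year
  stacks) warn or error as documented rather than returning silent
  nonsense.

## 7. Known limitations

* The predictive-process field is an approximation to the SPDE/GMRF
  construction; marginal variances at points far from knots are slightly
  attenuated, so field SDs estimated on very coarse meshes are mildly
  inflated to compensate. Matching the published 800-knot configuration
  coastwide is supported but not exercised in the default test run (runtime).
* AIC counts variance-type parameters but not random-effect levels;
  comparisons against tools using a different convention need care.
* No anisotropy, no barrier meshes, no geographic reprojection: all
  coordinates are planar km (UTM-style), and the projection tag is carried
  but never acted on.
* The RDA offers no permutation significance test by default and no
  partial RDA/CCA.
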