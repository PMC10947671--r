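---
title: "Coverage-standardized diversity mapping: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coverage-standardized diversity mapping: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hillmapr)
```

hillmapr estimates wild-plant species diversity surfaces from opportunistic
occurrence records (the kind citizen-science platforms produce), extrapolates
them to under-sampled areas by regression kriging, and quantifies
socioeconomic disparities in the resulting exposure surface at census-tract
level. This vignette explains the statistical machinery, the assumptions each
stage makes, and the choices we made where the design was genuinely open.

## 1. Why coverage standardization

Opportunistic records confound true diversity with sampling effort: a cell
with many observers accumulates species faster than an equally diverse cell
with few. Comparing raw species counts therefore maps effort, not ecology.
The package's answer is the standard one from modern diversity estimation:
convert records to *incidence* data, estimate *sample coverage* (the fraction
of the community's incidence probability mass belonging to species already
detected), and compare cells at a *fixed coverage* rather than fixed effort.

For each grid cell, the sampling unit is a distinct (observer, date) pair —
the finest unit consistent with counting "unique participants" and common
practice for opportunistic data (a plain per-observer rule is available via
`build_incidence(unit = "observer")`). With `T` units, incidence frequencies
`Y_i`, their sum `U`, and `Q1`/`Q2` the number of species seen in exactly
one/two units, coverage at observed effort is estimated by the Chao-type
estimator

    C(T) = 1 - (Q1 / U) * A,   A = (T - 1) Q1 / ((T - 1) Q1 + 2 Q2),

and at extrapolated effort `T + t*` by `1 - (Q1/U) * A^(t* + 1)`. When
`Q2 = 0` the usual `(Q1 - 1)` correction keeps the estimator defined. A cell
is *saturated* when coverage at **doubled** effort reaches 0.80 — doubling
probes whether the species-accumulation curve has levelled off rather than
rewarding sheer volume. Only cells with at least 40 unique observers are
assessed at all; these two rules (40 observers, 80% at 2T) are the
protocol's defaults and sit in `pipeline_config()` as overridable values.

Diversity is then reported as Hill numbers of order q = 0, 1, 2 (species
richness, exponential Shannon entropy, inverse Simpson concentration), all in
effective numbers of species, standardized to the effort `m*` at which the
coverage curve reaches 0.80. We invert the coverage curve by bisection to a
coverage tolerance of 1e-6. Standardization is applied to the
observed-effort coverage curve; the doubled-effort curve is used only for
the saturation decision.

### Rarefaction and extrapolation formulas

For effort `m <= T` (rarefaction) all three orders are computed from the
expected frequency counts under hypergeometric subsampling of the `T` units,

    Q_k(m) = sum_i C(Y_i, k) C(T - Y_i, m - k) / C(T, m),

with richness `S(m) = sum_i [1 - C(T - Y_i, m) / C(T, m)]`, entropy the
plug-in entropy of the expected counts, and the order-2 estimator the closed
form `(mU/T)^2 / (mU/T + m(m-1) sum_i Y_i (Y_i - 1) / (T(T-1)))`, which is
exactly the hypergeometric expectation below `T` and remains valid above it.
Non-integer `m` uses linear interpolation between integer efforts for every
order — interpolating all orders the same way is what preserves the ordering
`D0 >= D1 >= D2` at fractional efforts. Binomial coefficients are evaluated
through log-gamma.

For `m > T` (extrapolation): q = 0 uses the Chao2-type partial recovery of
undetected species; q = 1 blends the observed plug-in entropy toward an
asymptotic Chao–Wang–Jost-type incidence entropy estimate with weight
`(m - T)/m`, which is continuous at `m = T` and approaches the asymptote as
`m` grows; q = 2 uses the closed form above. Extrapolation is capped at
`2T` with a warning — beyond doubled effort these estimators are no longer
reliable, a standard caution in the rarefaction/extrapolation literature.

Two behaviors of the raw estimators deserve note. First, at very small
rarefied efforts the ratio-of-expectations construction can dip below one
effective species (for a monoculture, `S(1) = Y/T < 1`), and on the
extrapolation branch the three order-specific estimators are not mutually
consistent for very sparse cells. Because an effective number of species
below 1 is not interpretable and the ordering in `q` is a definitional
property of Hill numbers, `diversity_at_coverage()` floors its output at 1
and enforces the ordering by a cascade minimum; `hill_incidence()` exposes
the raw estimators untouched. On the interpolation branch (which is where
nearly all saturated cells land) both constraints hold exactly without any
adjustment.

Our tests validate the rarefaction formulas against exhaustive enumeration
over all unit subsets and against Monte-Carlo subsampling (the estimator
equals the Hill functional of expected frequency counts, so the subset
average is the exact target), and the coverage formulas against hand
evaluation.

## 2. The synthetic study system

All estimation stages are exercised on a generator with known ground truth;
no external data is needed anywhere. `sim_landscape()` builds a planar grid
of 5 x 5-km cells (synthetic coordinates are already projected; real
applications would first project to an equal-area CRS). Eleven covariate
surfaces (climate, elevation, evapotranspiration, vegetation index, canopy
and land-cover fractions, road density, soil properties) are unit-variance
Gaussian random fields with exponential covariance `exp(-d / range)`; the
default range of 25 km gives landscape-scale structure over ~5 cells. True
log-richness is a recorded linear combination of a subset of these surfaces
plus a spatially autocorrelated field (sd 0.15) plus independent noise
(sd 0.05), exponentiated around a median richness of 80 species. Each
cell's community is a lognormal species-abundance distribution (log-sd 1.5)
over a cell-specific subset of a 400-species pool; the true `D1` and `D2`
are computed exactly from the realized relative abundances, so
`D0 >= D1 >= D2 >= 1` by construction. The heavy lognormal tail is what
makes coverage estimation non-trivial: rare species keep `Q1` positive even
under heavy sampling.

`sim_occurrences()` draws observers per cell as Poisson with mean
proportional to a population-density surface (default 45 at average
density, so well-populated cells clear the 40-observer rule and remote ones
do not — the sampling bias the method exists to correct), gives each
observer a Poisson(20) number of records (the records-per-observer mean the
protocol reports; a negative-binomial alternative is configurable because
the real effort distribution is characterized only by its mean), and
samples species proportionally to the cell's relative abundances,
independently across records — the incidence model the estimators assume. A
configurable fraction of records (default 5%) is corrupted uniformly at
random with one of three defects (missing coordinates, genus-level
taxonomy, cultivated flag); corruption independent of species identity
makes the cleaning stage's expected removals exactly computable.

`sim_tracts()` tiles the grid with rectangular tracts (exact area
bookkeeping, no polygon dependency), aggregates truth area-weighted, and
attaches SES attributes on 0–100 scales. The primary SES variable
(unemployment) is an exact linear transform of tract-mean richness with
slope `1/ses_effect`, so the generating association is known precisely; the
default `ses_effect = -2` effective species per percentage point emulates
the inverse diversity–deprivation gradient at a realistic size for
tract-mean richness with sd ≈ 25–30. The remaining SES variables are
independent noise, a composite score flags the worst quartile as
disadvantaged communities (exactly `ceiling(0.25 n)` tracts), and counties
are contiguous tract blocks.

What the generator does *not* emulate — taxonomic misidentification,
trait-based recording preferences, seasonal reporting cycles, irregular
tract shapes, non-stationary covariate effects — bounds what green tests
mean: they demonstrate the pipeline recovers truth under its own stated
assumptions, not that those assumptions hold for any particular real
dataset.

## 3. Spatial models

Five extrapolation models are compared, mirroring common geostatistical
practice: ordinary kriging of the metric itself (OK), quasi-Poisson
log-link regressions (GLM, GAM), and regression kriging (GLM OK, GAM OK)
in which ordinary-kriged response-scale residuals are superimposed on the
trend. Residuals are kriged on the response scale because the composition
step is additive on that scale; a link-scale alternative would
exponentiate kriged noise and bias the mean.

Covariates are standardized (training statistics only, inside each CV
fold), then screened: collinear pairs (|r| > 0.8) lose the member with the
weaker outcome correlation, processed in descending |r| until none remains,
and predictors with |outcome correlation| <= 0.1 are dropped. Latitude is
excluded from the GLM's linear terms (collinear with longitude over a
coastline-oriented domain) but both coordinates enter the GAM through one
two-dimensional Duchon-spline smooth (`mgcv`, `bs = "ds"`, `m = c(1, 0.5)`),
the low-rank thin-plate-family smooth suited to spatial trends. GLM terms
are selected by both-direction stepwise quasi-AIC (dispersion fixed at the
full-model estimate); GAM smoothness is selected by REML with the
double-penalty option (`select = TRUE`) so whole smooths can be shrunk out.
In our pure-noise simulations the double penalty removes about half of the
irrelevant smooths outright and leaves the rest near one effective degree
of freedom, cutting total spurious edf by a factor of ~2.3 relative to
unpenalized REML — effective shrinkage, though not total elimination.

Residual semivariograms use the Matheron estimator in 15 lag bins up to
half the maximum pairwise distance, fitted by Cressie-weighted least
squares (`N(h)/gamma(h)^2`) over exponential, spherical and gaussian
families with non-negativity constraints and multi-start box-constrained
optimization; the family with the lowest weighted SSE wins. The kriging
system is solved globally (every training cell; dense solve is cheap at
these sizes), with a one-shot 1e-10 diagonal jitter retry on singularity.
The `range` parameter is the distance scale of each family (effective
range 3x for exponential). `gamma(0)` is 0 by the interpolation convention;
the nugget is the jump of the semivariogram at the origin. Final
regression-kriging predictions are floored at the minimum observed metric:
residual superposition must not produce diversity below anything actually
observed. Prediction standard errors combine the trend SE and the kriging
variance as independent components, `sqrt(se_trend^2 + var_OK)`; GAM SEs
are conditional on the selected smoothing parameters.

## 4. Validation and the optimized map

Model comparison uses 10-fold cross-validation with seeded random folds;
*everything* — standardization, screening, trend, residual variogram — is
refit on each fold's 90%. Held-out predictions are pooled before computing
correlation, MAE, RMSE and their relative versions (RMAE and RRMSE are
percentages of the mean observed value in the pooled validation set;
training metrics are averaged over folds). The selected model minimizes
validation RRMSE, with ties broken by higher correlation then lower RMAE,
and a consensus across the three metrics by majority (ties by mean RRMSE).
The final ("optimized") map keeps model predictions in unsaturated cells
and replaces saturated cells with their observed coverage-standardized
estimates — observations are strictly better than their own cross-validated
predictions, so this substitution cannot hurt accuracy to truth on average.

## 5. Tract disparity models

Cell maps are aggregated to tracts by exact area-weighted means of
intersecting cells (the "mean per tract" rule is not further specified in
protocol descriptions; area weighting is the unambiguous choice for
rectangles and is what a raster zonal mean approximates). Disadvantaged
versus other tracts are compared by Welch two-sample t-tests (the
unequal-variance default is the safer reading of an unqualified "t-test").
Associations at continuous scale use a linear mixed model per SES variable:

    metric ~ SES + population density + (1 | county) + spatially correlated error,

with an exponential correlation on tract centroids fitted by REML through
`nlme` (`corExp` within counties — county blocks are conditionally
independent given the random intercept). SES enters on its raw 0–100 percent
scale, so coefficients read "effective species per percentage point". Wald
95% intervals are reported. If the spatial fit fails to converge the model
falls back to independent residuals and flags it. Sensitivity analyses fit
the full model over education, linguistic isolation and unemployment
(poverty and housing burden stay out on collinearity grounds), run backward
elimination on ML-fit AIC (BIC reported alongside), and refit single-SES
models with the vegetation index as an extra confounder.

Two calibration notes from our simulations. With the spatial field drawn
within counties (matching the fitted covariance), the 95% CI covers a null
slope in ~92–95% of replicates; when the generating field crosses county
borders — dependence the grouped exponential structure cannot represent —
coverage drops to ~90%, a useful reminder that the model's SEs are only as
good as its covariance assumptions. Second, the SES slope estimated on
*mapped* (coverage-standardized, model-extrapolated) diversity is attenuated
relative to the slope built into *true* diversity, because standardized
diversity at 80% coverage is a compressed version of true richness; the
end-to-end recovery test therefore targets the tract-aggregated true metric.

## 6. Problem sizes and reproducibility

The shipped tests and the acceptance script run entirely on synthetic data
at desk scale, chosen to exercise every code path with comfortable margins:
estimator oracles on cells with up to 12 units and 15 species (where
exhaustive enumeration over unit subsets is exact), model-ranking
experiments on ten 40 x 40 landscapes with 400 training cells each,
coverage simulations with 200 replicates of 150 tracts, and full pipeline
runs on 12 x 12 to 24 x 24 grids. Every stochastic step is seeded from the
configuration; identical configurations reproduce run directories byte for
byte, and the run manifest records the package version, seeds and full
configuration needed to reproduce any artifact.

## 7. Known limitations

* The observer-day incidence unit is an assumption, not an inference; if
  real observers systematically split days across cells the effective unit
  changes.
* Extrapolated Hill numbers beyond observed effort mix estimators of
  different pedigree across orders; we cap at 2T and enforce order
  consistency, but extrapolated cells deserve the provenance flag they
  carry.
* Kriging uses stationary isotropic variograms; anisotropy (coastlines,
  mountain fronts) is not modeled.
* The disparity models are associational by design; no causal claims are
  supported, and confounders beyond population density (and optionally the
  vegetation index) are out of scope.
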