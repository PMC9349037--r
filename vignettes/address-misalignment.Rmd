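---
title: "Simulating address misalignment in air-pollution epidemiology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating address misalignment in air-pollution epidemiology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`addrsim` studies a practical question in air-pollution epidemiology: when a
cohort's residential addresses are only known to the district, how much do
health-effect estimates based on predicted exposure deteriorate relative to
complete addresses? This vignette describes the simulation model, its
assumptions, the tunable parameters, and the design decisions that were
genuinely open.

## The simulation model

One replicate runs through four stages.

**1. Geography (fixed over the whole simulation).** A square region of side
25 km (configurable) is tessellated into districts (bands split into
near-square cells), districts into neighbourhoods, and census-tract centroids
are scattered uniformly within neighbourhoods. Each district contains one
urban-background monitor and one governmental office at random positions;
roadside monitors are placed uniformly over the region; a regular lattice
provides grid centroids. Mothers' homes are tract centroids sampled with
replacement, per district, with probability proportional to the neighbourhood's
synthetic birth weight (Gamma(2,1) draws — right-skewed, strictly positive,
like real birth counts). Homes are sampled once and reused by every replicate,
mirroring a cohort whose addresses are fixed at baseline. The full-scale
defaults are 25 districts, 422 neighbourhoods, 16,230 tracts, 46,007 mothers,
25 + 12 monitors, 610 grid points; the desk-scale defaults (5 districts,
20 neighbourhoods, 800 tracts, 2,000 mothers, 5 + 3 monitors, 100 grid
points) make interactive work and the test suite fast.

**2. True exposure.** Annual-average PM₁₀ is a Gaussian random field
\[
X(s) = \mu + z(s)^\top\beta + \eta(s) + \varepsilon(s),
\]
with overall mean $\mu = 52\ \mu g/m^3$, standardized geographic covariates
$z(s)$, an exponential-covariance process $\eta$ (partial sill $\sigma^2$,
range $\phi$) and independent nugget noise $\varepsilon \sim N(0, \tau^2)$.
Eight scenarios ES1–ES8 span the published combinations of
$(\tau^2, \sigma^2, \phi)$, from "little mean structure, dominant spatial
variability" (ES1) to "dominant mean structure" (ES8, the parameter set
estimated from Seoul monitoring data). The field is drawn **jointly** at every
location — monitors, offices, centroids, grid, mothers — so predictions and
truth refer to one surface. Mothers sharing a tract centroid share its
spatially-correlated component but receive independent nugget draws: the
nugget is non-spatial (micro-scale/measurement) variability.

**3. Outcome.** LBW status is Bernoulli with
$\operatorname{logit} P = \alpha + \beta X$, $\beta = \ln(1.0033)$ per
µg/m³. The intercept is not a free parameter: it is recalibrated per
replicate by monotone root finding so the cohort-mean probability equals the
baseline prevalence (default 5%, a typical LBW proportion; the source
proportion is not published). The relative risk is interpreted per 1 µg/m³,
consistent with the magnitude of the published estimates; the increment is
configurable.

**4. Prediction, assignment, and inference.** Monitors observe the field;
NM/IDWA/AA use the background monitors only, LUR/UK all monitors, matching
the published design. The universal-kriging variogram is re-estimated every
replicate from the monitor values (after OLS detrending on the covariates, a
standard choice when the field has drift — switchable). Ten exposure vectors
feed logistic fits, and replicates aggregate to mean RR, bias, RMSE, ASE
(all slope-scale, displayed ×100), coverage probability, and TPR (the ratio
of significantly *positive* findings under predicted vs true exposure,
two-sided p < 0.05 and positive slope).

## Calibrations that the source leaves open

* **Correlation family and range convention.** The variogram family behind
  the published parameters is not stated. We use the exponential model with
  the *practical-range* convention, $\rho(h) = \exp(-3h/\phi)$ — the dominant
  convention in air-pollution geostatistics — and expose
  `convention = "parameter"` ($\rho = \exp(-h/\phi)$) as a switch.
* **Mean-structure coefficients.** The five geographic covariates and their
  coefficients are not published. We synthesize five smooth standardized
  surfaces (superposed Gaussian bumps at two length scales, deterministic in
  the coordinates so coincident points always agree) and give the scenarios a
  *variance-share* target instead of fixed coefficients: the covariate term
  contributes 0% (ES1–ES4), 40% (ES5–ES6) or 70% (ES7–ES8) of total
  variance. Equal-magnitude, alternating-sign loadings are rescaled against
  the empirical covariate covariance over mothers so the realised share is
  exact. Under this calibration the full-scale per-replicate SD of mothers'
  true exposure falls in the published 4.66–6.45 µg/m³ band (≈5.9 µg/m³ under
  ES8 at the acceptance scale).
* **Birth weights.** The real distribution of births across neighbourhoods is
  unpublished; weights are synthetic and configurable.

## Numerical choices

* The spatial component is simulated by Cholesky factorization of the
  no-nugget covariance over *unique* coordinates (mothers map onto their
  tract centroids), with relative jitter $10^{-8}\sigma^2$; the factor is
  computed once per scenario and reused by all replicates. Dense
  factorization makes full-scale (~63k unique points) runs infeasible; use
  the reduced configurations, which preserve every structural feature.
* Variogram fitting is bounded WLS from a deterministic 5×5×5 multi-start
  grid. Two weighting schemes are available: Cressie weights
  ($N_j/\gamma_j^2$, default — appropriate for the roughly balanced
  equal-width bins used on monitor data) and gstat-style $N_j/h_j^2$ weights,
  preferable when pair counts are strongly unbalanced across bins (e.g.
  geometric bins over a nested design), where count-dominated long-distance
  bins would otherwise swamp the short-range information. Empirical
  variogram bins are represented by their mean pair distance, not the
  midpoint, which removes a fit bias when bins are wide. If every start
  fails, moment estimates are returned with a `fallback` flag, counted in the
  run manifest.
* The kriging predictor targets the smooth surface (nugget-free covariance to
  targets): it interpolates exactly when $\tau^2 = 0$ and collapses to the
  GLS/OLS drift regression as $\sigma^2 \to 0$. With few monitors and a short
  range (ES7/ES8 at desk scale), the fitted partial sill is frequently ~0 and
  UK then coincides with LUR — a faithful consequence of the model, not a
  defect: monitor spacing simply cannot resolve a 1-km range.
* Logistic fits use IRLS to $10^{-12}$; non-identifiable fits (e.g. constant
  exposure in a one-district region) become flagged non-converged results
  that summaries exclude and count.
* Seeds: per-(scenario, replicate) seeds derive from the master seed and the
  scenario's global identity by a fixed counter scheme, so subset runs and
  checkpoint-resumed runs reproduce identical results.

## What the tests do and do not show

The test suite checks the machinery against independent oracles (dense
GLS-form kriging solves, Newton-Raphson logistic maximization, brute-force
pair arithmetic for variograms, closed-form quadratic-form moments for
cohort variance) and the study-level operating characteristics at these
scales:

* effect recovery: ES8, 5,000 mothers, 1,000 replicates — TE mean RR within
  ±0.001 of 1.0033, bias×100 within ±0.1 of 0;
* coverage: 2,000 mothers, 1,000 replicates — CP within ±0.02 of nominal for
  TE (ES2), UK and UKCA (ES8);
* directional findings: ES8, 5,000 mothers, 500 replicates — AA/UKD attenuate
  (negative bias, larger than UKCA's in magnitude), district methods lose
  power relative to complete-address UK, and within-district aggregation
  (UKNA/UKCA/UKGA) shrinks exposure variability relative to the UK surface;
* variogram recovery: one 1,500-point ES1 field on a nested design (375
  nodes, two 40 m satellites, one 250–5,500 m satellite each) recovers
  (nugget, partial sill, range) within 25%.

The synthetic geography reproduces the *structure* of the real study —
hierarchical administrative units, one background monitor per district,
mothers at tract centroids, birth-weighted sampling — but not its actual
monitor placement, boundary shapes, covariate fields or birth distribution.
Quantities that depend on that geometry (method-specific bias magnitudes,
correlations between predictions and truth) therefore reproduce the published
*orderings and signs* rather than exact values; quantities that do not (TE
rows, coverage probabilities) reproduce the published numbers. Two published
patterns are geometry-sensitive in our region: SD(UKD) can exceed SD(UK)
because five office predictions extrapolate the drift, and SD(AA) ≈ SD(NM)
because each district has exactly one background monitor.

## Known limitations

Temporal variation, indoor/personal exposure, mobility, confounders and
multi-pollutant error correlation are out of scope. The health model is a
correctly specified logistic regression, so TE coverage is nominal by
construction; coverage under predicted exposure reflects measurement-error
structure, not model misspecification. Full-scale dense simulation requires
an iterative/conditional simulator that the package intentionally does not
include.
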