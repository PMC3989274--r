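---
title: "Methods: semimonthly hurdle habitat models from aerial surveys"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: semimonthly hurdle habitat models from aerial surveys}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`winterhab` models the winter distribution of North Atlantic right
whales on their southeastern US calving ground from line-transect
aerial surveys. This vignette records the model, its assumptions, the
tunable parameters, the synthetic world used for testing, and the
numerical and design choices a maintainer would want to know about.

## The model

The response is the number of whales sighted in a *sampling unit*: one
grid cell summarised over one semimonthly period (days 1–15 of a month
are half "A", day 16 to month end half "B"; each season runs December A
through March B, eight periods). Roughly 96% of units hold no
sightings, so occurrence and positive abundance are modelled separately
(a hurdle) and multiplied:

* **Occurrence** — quasibinomial GAM with logit link on the presence
  indicator of every included unit. The quasi family absorbs the
  overdispersion created by false absences (submerged whales, observer
  error) and spatial aggregation.
* **Positive abundance** — Gamma GAM with log link on the integer
  whale count of units with at least one sighting, used exactly as a
  positive continuous response (no continuity correction). This is a
  modelling convenience for a small, skewed positive count.
* **Relative abundance** — the product of the two component
  predictions at a fixed reference survey effort. It is *relative*
  because sightings are not corrected for availability or perception
  bias and whales may be counted again on later surveys in the same
  period.

Every smooth is a penalized cubic regression spline **with shrinkage**
(`mgcv` basis `"cs"`) at basis dimension `k = 3`, capping each term at
2 effective degrees of freedom; the cap keeps responses ecologically
interpretable and the shrinkage lets unsupported terms vanish entirely.
Smoothing parameters minimise the GCV score `n·D/(n − edf)²`. The
migration signal enters as a tensor product of `k = 3` marginal bases
in semimonth ordinal and northing; survey year is an unpenalized
factor. Survey effort enters the occurrence model as a smoothed
covariate rather than an offset, because the effort–sighting
relationship plateaus (near 250 km² per unit) instead of staying
linear.

### Effort correction

Each on-effort track segment is buffered on both sides by the
*effective search width* of its platform and sea state. Detection is
half-normal, `g(x) = exp(−x²/2σ²)`, with log-linear sea-state
dependence `σ(z) = exp(β₀ + β₁ z)`, fitted per platform by maximising
the conditional likelihood `Π g(x_i)/μ(z_i)`, where
`μ(z) = ∫₀^W g` is evaluated in closed form through the normal CDF
(`σ√(2π)(Φ(W/σ) − ½)`). Quadrature is unnecessary: the half-normal
integral is exact, and tests verify the closed form against Simpson
integration at 10⁵ panels. The searched area of a segment of length L
is `L · 2(ESW − blind)`, with a 0.186 km blind strip per side for the
flat-window platform and none for the bubble-window one. Truncation
defaults to the per-platform 95th percentile of distances when not
supplied (standard distance-sampling practice; the analysis this
package re-implements does not state one).

### Selection and validation

Forward stepwise selection starts from the null model; at each step the
candidate with the lowest GCV advances, and is accepted only if (i) its
GCV is below the previous step's, (ii) the analysis-of-deviance F-test
`((D_prev − D_new)/Δedf)/φ_new` on `(Δedf, n − edf_new)` df improves
the model at α = 0.05, and (iii) its ±2 SE pointwise partial-effect
band excludes zero somewhere in the observed range. F-tests use the
*larger* model's dispersion and refitted smoothing parameters for every
candidate. GCV ties break by fewer edf, then candidate order.
Cross-validation is five *independent* 80/20 splits (not a partitioned
5-fold), scoring mean squared prediction error on the component's
response scale: probability against the 0/1 indicator for occurrence —
which is why occurrence ASPE is two orders of magnitude smaller than
abundance ASPE — and counts for abundance.

### Prediction, residuals, autocorrelation

Hindcast maps override effort to 250 km² everywhere and never
extrapolate: units with any covariate outside the component's training
range, missing SST (cloud), invalid depth, or an unseen year level are
masked with a recorded reason. The product's standard error uses the
delta method under component independence,
`Var(p·E) ≈ p²Var(E) + E²Var(p)`; the components are fitted on
overlapping data, so this is an approximation.

The composite deviance residual of a unit with observed count y and
predicted relative abundance μ is the signed square root of the Gamma
deviance `2(−log(y/μ) + (y−μ)/μ)` when y > 0, and
`−√(−2 log(1−p̂))` when y = 0 (the occurrence component's deviance
contribution, negative because the observation sits below the
prediction). This composite definition is a package choice; the
two-part model has no canonical single residual. Global Moran's *I*
with unstandardized inverse-distance weights (`w_ij = 1/d_ij`, all
cells neighbours) is computed per semimonth on these residuals; a
row-standardized variant is available (and is what `ape::Moran.I`
computes, used as a cross-check in the tests). The reported z-score
uses the normality-assumption variance.

### Calf segregation

Environmental conditions at *exact sighting locations* (native-pixel
depth and daily SST, point distances) are compared between groups with
and without calves by Mann–Whitney tests: midranks for ties,
tie-corrected variance, continuity-corrected normal approximation, and
exact enumeration of all group assignments when n₁+n₂ ≤ 12. "Sequential
Bonferroni" for the eight per-semimonth northing comparisons is Holm's
step-down rule (ordered p(i) vs α/(m−i+1), stop at first failure).
Records with depth above sea level are excluded; a third "other"
demographic category, when flagged, is excluded from both groups. Exact
and normal p-values cannot agree to better than ~0.015 at n₁ = n₂ = 6:
the discrete U lattice at N = 12 is simply that far from a normal, so
the enumeration audit in the tests asserts the documented 0.02 bound
rather than a tighter one no convention attains.

## The synthetic world

The generator emulates the structure of the real survey programme so
the whole pipeline is testable with known truth:

* **Geometry** — a 55.6 × 240 km coastal strip; east–west transects
  every 5.56 km in the southern half, northwest–southeast transects
  every 7.52 km in the north; flat-earth projected km throughout (at
  this scale projection error is irrelevant).
* **Environment** — a shelf deepening monotonically offshore to 45 m
  with along-shore ripple, a gently sinuous shoreline, and daily SST =
  seasonal base (17 °C early-season, dipping 3 °C mid-winter) +
  per-season anomaly + north–south gradient (−0.0125 °C/km) + a warm
  Gulf Stream band centred 70 km offshore (amplitude 12 °C) + smooth
  mesoscale noise (sd 1 °C, 20 km scale). The rasters extend 30 km east
  of the surveyed strip, as satellite imagery does, so the 22 °C
  isotherm exists even when it lies beyond the transects; in-survey
  isotherm distances are consequently almost never negative, matching
  the region's winters. Cloud masks are thresholded smooth random
  fields (spatially coherent, ~30% cover per image), eight images per
  semimonth.
* **Whales** — latent occurrence logit = intercept (−7.6, calibrated
  so ~96% of sampled units are empty) + season intercept + a Gaussian
  SST bump (peak 14 °C, sd 2.5, amplitude 2.5) + exponential nearshore
  preference (scale 25 km, amplitude 2) + mid-depth bump (18 m) + a
  tanh isotherm-avoidance response + a migration term
  `northing × cos(2π(sm−1)/7)` placing whales north early and late in
  the season and south at mid-season. Positive group sizes are
  `1 + Poisson(m − 1)` with the mean m coupled to the same habitat
  response (gain 0.35, centred so occupied-cell group size averages
  ~2.2 whales): better habitat holds slightly larger groups, giving the
  abundance component a real (if weak) signal, as the analysis being
  emulated found. Each occupied cell-period holds one group, a cow-calf
  pair with probability 0.41.
* **Observation** — 18 southern and 5 northern flights per semimonth
  (daily-coverage scale, so unit effort brackets the 250 km² reference
  and occasionally exceeds the 340 km² outlier threshold); per-flight
  sea state, altitude and visibility, with 8% of flights violating an
  on-effort rule; half-normal detection thinning with per-platform
  coefficients chosen to give effective search widths of ~1.2–2 km;
  duplicate (4%), verification (3%) and off-effort-at-first-detection
  (3%) records injected at fixed rates so filter accounting is exactly
  predictable.

What the generator does **not** emulate: aircraft dynamics,
availability/perception bias, photo-identification, Gulf Stream
physics, or inter-group spatial interaction. A green end-to-end test
therefore establishes that the pipeline recovers a known smooth habitat
response under realistic sampling noise — not that the model is correct
for real whales.

Two-season test worlds use anomalies of −1.5 and +1.5 °C (a cold and a
warm season), the contrast that identifies the SST response separately
from the static spatial gradients and drives the southward shift of the
predicted distribution in cold years.

## Numerical choices and degenerate inputs

* Detection fitting: Nelder–Mead from three starts (`β₀` at
  `log sd(x) ± 0.5` and 0, `β₁ = 0`), best-of rule; convergence failure
  reported with the numerical gradient norm; all-zero distances and
  fewer than 20 truncated observations are errors.
* Grid assignment: cell intervals are right-closed, so a point exactly
  on a shared edge belongs to the lower cell id; the zone boundary
  belongs to the southern zone; the boundary is snapped to a whole
  number of southern rows so the zones tile without gaps.
* Segment clipping: exact parametric splitting at cell boundaries;
  swath area is apportioned proportionally to in-cell track length,
  which equals the buffer-overlay answer for straight segments away
  from swath ends. Where buffered swaths of adjacent transects would
  overlap at corners, this length-proportional rule is the documented
  arbitration.
* Marching squares: saddle squares resolved by the cell-centre mean;
  a cell at exactly 22 °C gets a non-negative signed distance (the
  negative sign is reserved for strictly warmer water); a domain with
  no isotherm yields missing distances and flagged units.
* Cells partially outside a raster use available pixels when coverage
  is at least 50% (depth/slope); SST cells accept any cloud-free pixel.
* GAM fits: `mgcv` with `method = "GCV.Cp"`, `epsilon = 1e-10`; fixed
  smoothing (`sp`) bypasses selection and `sp = 0` reproduces the
  unpenalized GLM to ~1e-8, verified against a hand-written IRLS in the
  tests. Quasibinomial data with a single season drop the year factor
  (no interannual contrast to estimate). Degenerate responses
  (all-zero/all-positive presence, constant positive counts) are
  explicit errors.

## Limitations

* The year factor permits hindcasts only; seasons outside the training
  data are masked, and forecasting would require replacing the factor
  with a demographic covariate.
* The delta-method SE of relative abundance ignores the dependence
  between components fitted on overlapping data.
* The Gamma-on-integer-counts abundance component and the composite
  residual definition are pragmatic conventions, not likelihood-exact.
* GCV smoothing selection can undersmooth relative to REML;
  REML/thin-plate/autocorrelated alternatives are deliberately out of
  scope to keep the engine faithful to the analysis being
  re-implemented.
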