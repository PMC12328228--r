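---
title: "Quantifying forest edge effects on surface temperature: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying forest edge effects on surface temperature: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(forestedge)
```

## The problem

Satellite-sensed land-surface temperature (T_surf) over forest measures the
canopy-top leaf surface. Near a forest edge, T_surf changes systematically:
typically it rises from the forest interior towards the edge and into the
surrounding open land, with the curve flattening a few hundred metres inside
the forest. `forestedge` implements the full inference chain for this edge
effect at 30 m pixel resolution:

1. classify forest from canopy cover, compute exact signed Euclidean
   distances to the nearest edge, and sample points per satellite
   scene-by-overpass (SxO);
2. fit an additive model of T_surf against distance from the edge,
   controlling for elevation and per-SxO offsets, and derive partial
   edge curves and edge-interior contrasts with standard errors;
3. summarize each SxO by the slope of T_surf on log10(distance) inside the
   forest, and relate these slopes to scene macroclimate with an
   inverse-variance weighted quadratic meta-regression;
4. compare T_surf to the thermal optimum for ecosystem productivity
   (T_opt) as a function of edge distance.

Because global 30 m rasters are not practical inputs for a test suite, the
package ships a synthetic-landscape generator with *known ground truth*.
Every stage of the chain is validated by recovering that truth.

## The synthetic landscape generator

Each scene is a square grid of 30 m pixels. Forest patches are unions of
random disks (log-normal radii around `patch_scale`); canopy cover is drawn
high inside patches and low outside, so the 30 % classification threshold
reproduces the patch geometry. The noise-free temperature at signed edge
distance $d$ (negative outside the forest, positive inside) is

$$T(d) = T_\mathrm{macro} - A\,S(d) + \ell\,(e - \bar e) + \gamma_{so},
\qquad S(d) = \frac{1}{1 + e^{-d/\lambda}},$$

where $A$ is the edge amplitude (non-forest minus deep interior, °C),
$\lambda$ the sigmoid length scale, $\ell$ the elevation lapse rate applied
about the scene-mean elevation, and $\gamma_{so}$ an additive per-SxO offset.
I.i.d. Gaussian noise (`sigma_noise`) and Bernoulli cloud dropout complete
the observed fields. The logistic profile is a deliberate design choice: the
empirical curves it emulates flatten by roughly 500 m but carry no published
functional form, and a single sigmoid covers both sides of the edge and
yields closed-form contrasts, $T(d_1)-T(d_2) = A[S(d_2)-S(d_1)]$, against
which fits can be checked exactly.

Default study conditions (chosen once, as the conditions the analysis
targets, and used by the test suite):

| parameter | default | meaning |
|---|---|---|
| `pixel_size` | 30 m | Landsat-class resolution |
| `n_points_per_sxo` | 1000 | random points drawn per SxO |
| `canopy_threshold` | 30 % | inclusive forest classification |
| `max_edge_distance` | 1000 m | point retention limit |
| `lam` | 90 m | edge curves saturate (>99 %) by ~500 m |
| `lapse` | −0.0065 °C/m | standard environmental lapse rate |
| `sigma_noise` | 1.5 °C | per-point retrieval + microsite noise |
| `sigma_scene` | 2 °C | between-overpass weather variability |
| `cloud_fraction` | 0.1 | typical usable-scene cloud contamination |
| `a0, a1, a2` | 0.4, −0.05, 0.004 | macroclimate link $A = a_0+a_1T+a_2T^2$ |

Scene baselines follow latitude, $T_\mathrm{macro} = 28 - 0.35\,|lat| +
\varepsilon$, so biome labels (|lat| ≤ 23.5° tropical, ≤ 50° temperate,
beyond boreal) and macroclimate are consistent. Seasons are
hemisphere-flipped meteorological quarters of the overpass month. A
`winter_reversal` switch shifts the amplitude of boreal winter overpasses
negative, emulating the observed sign flip where snow-free forest is warmer
than its surroundings in winter. All randomness derives from one root seed
through per-scene hashed streams, so any scene is reproducible in isolation.

What the generator does **not** emulate: real edge geometry inherited from
land-use history, spatially correlated retrieval error, emissivity and
view-angle artefacts, phenology-dependent amplitudes within a season, and
topographic edge alignment. Passing recovery tests therefore demonstrates
the *estimators* are correct and well calibrated under the stated noise
model — not that the scientific conclusions transfer to any particular real
landscape.

## Edge geometry

Distances are measured between pixel centres, so the smallest attainable
in-forest distance is one pixel (30 m) — consistent with evaluating the
"edge" at 30 m. The transform is an exact Euclidean distance transform
(Felzenszwalb–Huttenlocher, implemented in C++); the test suite asserts
exact agreement with a brute-force all-pairs search, since an approximate
transform would bias the short-distance end of every curve. The 30 %
canopy threshold is inclusive. Points are sampled uniformly *without*
replacement within an SxO (duplicate coordinates would distort Moran's I),
then filtered — cloud, missing data, |d| > 1000 m — in that order, so
retained counts vary between SxO as they do in practice. Curve fitting
further restricts to d ≤ 500 m inclusive; non-forest points (down to
−1000 m) are kept to anchor the open-land end of the curve.

## The additive curve model

The model is

$$T_i = \beta_0 + f_d(d_i) + f_e(e_i) + u_{s(i)} + \epsilon_i,$$

with cubic B-spline smooths for distance (20 basis functions over
[−1000, 1000] m) and elevation (10 basis functions over the data range),
both under second-difference penalties, and per-SxO effects $u_s$ under a
ridge penalty — the standard penalized-regression representation of an
additive random intercept. Basis dimensions resolve the ~500 m curve shape
at 30 m data spacing; sum-to-zero constraints (absorbed by a QR
reparameterization) identify the smooths against the intercept.

Smoothing parameters minimize GCV, searched by coordinate descent over a
20-point log-spaced grid per term (10^−4 to 10^6, up to four sweeps —
deterministic, and cheap because the normal equations are precomputed once).
REML is selectable (`method = "REML"`, profiled Gaussian form). The
coefficient covariance is $\hat\sigma^2 (X^\top X + P_\lambda)^{-1}$ with
$\hat\sigma^2 = RSS/(n - \mathrm{edf})$.

**Partial curves.** Predictions run every metre from −200 to 500 with
elevation at its sample mean and the SxO effect at the most frequent unit
(ties broken by first level), leaving only the distance effect. Predictions
refuse to extrapolate outside the knot support.

**Contrasts.** The edge-interior contrast is the difference of partial
predictions at 30 m and 500 m (variant: 50 m vs 1000 m, which requires the
model fitted on the full 1000 m point set). Two SE conventions are always
computed: the literal source formula
$\sqrt{SE_\mathrm{edge} + SE_\mathrm{interior}}$ ("as-printed"), and
conventional quadrature $\sqrt{SE_\mathrm{edge}^2 + SE_\mathrm{interior}^2}$.
Whether the printed formula is a typo for quadrature cannot be resolved from
the text, so the as-printed rule is the fidelity default and every contrast
object carries both numbers. Note the ordering of the two comparisons is
length-scale dependent: for $\lambda \gtrsim 150$ m the wider 50/1000
comparison captures more of the amplitude, while for short length scales
starting at 50 m forfeits the steepest part of the curve and 30/500 is the
larger contrast.

**Residual diagnostics.** Moran's I uses inverse-Euclidean-distance weights
(zero diagonal, row-standardized; coincident points would receive the
weight of the nearest non-coincident pair), a random subset of at most
`max_points` residuals, and a 999-permutation test (one-sided towards
positive autocorrelation by default). Dense weights cost O(n²) memory, so
the pipeline's diagnostic subset defaults to 2000 points; the function
accepts larger caps where memory allows.

## Per-scene slopes and the macroclimate meta-regression

Within each SxO, T_surf is regressed on log10(distance) and elevation over
in-forest points (0 < d ≤ 1000 m; the 30 m pixel floor bounds the
regressor). Units with fewer than 4 observations or a degenerate distance
column yield rejection records, not errors; an aliased elevation column is
dropped. Exact noiseless fits would give a zero slope variance, which the
inverse-variance weights cannot accept, so stored variances are floored at
machine epsilon.

Outliers are removed by a one-pass Hampel filter: slopes outside
median ± 3·MAD, with MAD the *unscaled* median absolute deviation (the
construction the Hampel identifier names); a `mad_type = "mean"` switch
provides the mean-absolute-deviation-about-the-median reading. A zero MAD
degenerates the interval to the median alone, and every off-median slope is
removed with a warning.

The meta-regression is weighted least squares of the slope on scene-mean
temperature and its square, weights $1/\mathrm{var}(\beta)$; SEs come from
the weighted normal-equations inverse scaled by the weighted residual
variance, and the weighted R² is $1 - RSS_w/TSS_w$ with the total sum taken
about the weighted mean (stated explicitly because R² under weights is
convention-dependent). Scene-mean temperature is the arithmetic mean over
*all* the unit's retained points, inside and outside the forest — also for
the cooling-only subset (slopes < 0), which mirrors the robustness variant
restricted to scenes whose interior is cooler than the edge. An unfiltered
variant is provided alongside.

**Sign convention.** Distance increases into the forest, so interior
cooling means a negative slope. Where the macroclimate link is stated as an
amplitude relation $A(T) = a_0 + a_1 T + a_2 T^2$ with $a_2 > 0$ ("stronger
cooling under warmer macroclimate"), the corresponding statement about
slopes holds on the *edge-effect strength* scale $-\beta$: the per-scene
slope is approximately $-\kappa A$ with $\kappa > 0$ a scene-specific
projection factor of the sigmoid onto log-distance. The meta stage therefore
reports both scales. Because $\kappa$ depends on each scene's sampled
distance distribution, the landscape path recovers the *sign* and shape of
the quadratic link, while exact coefficient recovery is tested at the slope
level where the truth is well defined.

## The productivity temperature gap

T_opt values live on a coarse grid (defaults to 960 m cells over the scene
tiles; 1/12° in the real-data setting). Lookup is containment, not
interpolation, with half-open cells: a point on a shared vertical boundary
belongs to the eastern cell, on a horizontal boundary to the southern one.
Points on undefined cells are dropped and counted. A scene enters the gap
analysis iff it has ≥ 500 in-forest observations from ≥ 2 overpasses with
≥ 1 observation at ≥ 800 m (all inclusive); the filter is monotone in the
point set. The gap model reuses the curve machinery with response
T_surf − T_opt on in-forest points, predicting 0–500 m. When T_opt is
constant the gap curve equals the temperature curve minus that constant
exactly, a conservation identity the tests assert.

The synthetic T_opt grid has two modes: `uniform`, and
`offset-from-interior`, where cells covering a scene hold the scene's
deep-interior noise-free temperature plus an offset — so the deep-interior
gap is minus the offset by construction. Offset −2 °C emulates a
tropics-like regime (both edge and interior above the optimum, edge more
so); offset 0 a boreal/temperate-like regime (interior near the optimum).
Gap-scenario studies use `sigma_scene = 0.3` °C: the reference-unit offset
enters the pinned prediction directly, and a large between-overpass spread
would swamp the scenario's target gap with a quantity the model is not
trying to estimate.

## Pipeline

`run_pipeline()` executes synth → curve → meta → gap → report, exchanging
CSV files so each stage can be re-run from its inputs, and writes a
manifest (configuration snapshot, root seed, MD5 digests, row counts, and a
removal ledger in which cloud, nodata, distance, eligibility and Hampel
removals each appear exactly once and reconcile to totals). Curve and
contrast models are fitted independently within each biome-by-season group;
groups with fewer than 2 SxO or 50 points are skipped with a warning
record. Configuration is YAML with a full default set; unknown keys are
errors. A thin command-line wrapper (`inst/cli/fet`) exposes the stages as
subcommands.

## Numerical choices and degenerate inputs

- B-spline knots are uniform and extend three intervals beyond the range,
  so an infinite distance penalty drives the curve to a straight line (the
  penalty null space) — a limit the tests check. Evaluations at the exact
  support boundary are clamped against one-ulp drift.
- Cholesky pivots below √ε·max flag rank deficiency; the error names the
  offending term. A constant elevation column drops the elevation smooth.
- The raster container is a plain matrix with origin/pixel-size metadata;
  file interchange uses the ESRI ASCII grid format, a standard plain-text
  single-band raster carrying exactly that metadata.
- Problem sizes in the test suite (e.g. 50 scenes × 1000 points for curve
  recovery, 300 scenes for meta-regression recovery, 2000-point Moran
  subsets, a 12-scene demo pipeline) were chosen as the smallest designs at
  which the recovery properties are comfortably identifiable.

## Known limitations

- The scene random effect is ridge-penalized with a single shared
  smoothing parameter; heteroscedastic scene variances are not modelled.
- Moran's I is a diagnostic only; no autocorrelated error model is fitted.
- The generator's flat local grid ignores projection and geodesic effects;
  scenes are tiled along one axis for coordinate uniqueness, not geographic
  realism.
- GCV can undersmooth at very large n; REML is available where that
  matters.
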