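---
title: "Leaf shape quantification and canopy light simulation: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Leaf shape quantification and canopy light simulation: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette explains the models implemented in `leafshape`, the choices
made where the design was genuinely open, and what the synthetic-data tests
do and do not demonstrate about real recordings.

## The leaf shape model

Maize blade outlines are described by a two-parameter sine function. With
`l` the relative distance from the leaf tip (0 = tip, 1 = base) the
relative width is

$$ w(l) = \left[\sin\!\left(\frac{\pi\, l}{2a}\right)\right]^{\alpha} . $$

The *ratio factor* `a` is the relative position of the maximum width
(`w(a) = 1`); the *shape factor* `alpha` controls how fast the blade
narrows: large `alpha` gives narrow, lanceolate blades, small `alpha`
nearly parallel-sided ones. The argument is written `pi * l / (2a)` —
placements that scale `l` differently would not put the maximum at `l = a`,
which is the property that defines `a`. Parameter domain: `alpha > 0` and
`0.5 <= a <= 1`. The lower bound for `a` is admitted as a closed bound so
that the elliptic blade (`a = 0.5`, widest at mid-length, zero width at
both ends) is representable; the fitter keeps its lower bound open at 0.5.

**Fitting.** `fit_shape()` performs bounded Levenberg–Marquardt least
squares (`minpack.lm::nls.lm`) in the box `alpha` in (0, 5], `a` in
(0.5, 1], starting from `(0.85, 0.70)` — the fixed values in common use for
maize. If the first start does not converge, the fit restarts from the four
corners of the box (moved slightly inside) and keeps the converged solution
with the lowest residual sum of squares. The tip sample, when present,
enters the fit with the same weight as every other point. Goodness of fit
reports RMSE together with an adjusted R² obtained by regressing observed
on estimated widths *with intercept* — a deliberate choice where both
conventions exist — and adjusting for the two model parameters.

**Leaf area coefficient.** Integrating `w(l)` gives the fraction `c` of the
bounding rectangle occupied by the blade, so that
`area = length * width * c`. The default rule evaluates the 100-step
fixed-grid sum at `l = 0.01, 0.02, ..., 1.00` and averages; a trapezoidal
rule is available. The fixed grid is retained as the default because
downstream width adjustment is defined against this convention
(`c(0.85, 0.70) = 0.75` at two decimals); the sum sits within 0.005 of
adaptive quadrature over the whole parameter range used here.

**Width adjustment.** Comparing shapes at constant leaf area uses
`width_adj = length * (1/LWRatio) * (0.75/c)`, with 0.75 the reference
coefficient. The identity
`leaf_area(length, width_adj, c) = length^2 * 0.75 / LWRatio` is exact and
independent of shape, which is what lets the canopy experiment isolate
shape from area.

## Synthetic data: what is emulated

`make_leaf_mask()` rasterizes a leaf silhouette drawn from the shape family
(column 1 = tip), recording for every pixel column both the continuous
width implied by the shape function and the pixel count actually drawn.
Two details matter:

* the midrib row is drawn wherever the blade has any width, because the
  apex of a physical leaf flattened under pressure rollers remains visible
  to a camera even where the blade half-width falls below one pixel;
* interior defects (holes, fissures) are carved *after* the ground-truth
  table is computed, so defects change the mask but never the outer-width
  truth — the reference for the pipeline's defect-invariance contract.

`render_video_frames()` places the mask and one filled circular reference
marker (known diameter 2.47 cm, distinct greenish hue) on a virtual
conveyor moving at a constant, configurable speed (default frame geometry
1920×1080 at 60 fps, as in the recording setup the pipeline targets; tests
use smaller frames). One leading marker is used: the detector takes the
first qualifying object scanning bottom-to-top, so a single marker ahead of
the leaf suffices. All randomness (edge jitter, pixel noise) sits behind
one integer seed per artifact; rendering is byte-identical per seed.

The generator does *not* emulate perspective or lens distortion, specular
highlights, leaf curl (the physical device flattens leaves), motion blur,
or non-uniform lighting. Passing the round-trip tests therefore
demonstrates the correctness of the measurement logic — assembly,
calibration, contour extraction, width counting — not robustness to every
optical artefact of a real camera.

`make_weather()` provides constant or sinusoidal daily min/max temperature
series. The simulation default is a constant 12/20 °C day, i.e. 8 °Cd of
thermal time per day above the 8 °C base — a typical mid-season mean that
brings all 17 leaf ranks out by day 64 and near-full expansion by day 81.

## The vision pipeline

1. **Assembly.** Per-frame displacement is estimated by 1-D
   cross-correlation of foreground column profiles of successive frames.
   Only frame pairs whose foreground is substantial and fully inside the
   frame are used — clipped objects bias the correlation peak toward zero —
   and the marker-only profile is tried first, since the compact marker
   remains fully visible for most of its transit even when the leaf is
   longer than the frame. The belt speed is taken as the median over usable
   pairs (the belt is mechanically constant); a known speed can be supplied
   to skip estimation. Travel direction is detected from the sign, so
   reversed frame order assembles identically.
2. **Calibration.** Marker candidates are hue-classified connected
   components with circularity `4A / (pi D^2) >= 0.85` (`D` the larger
   bounding-box side), scanned bottom-to-top. The detected width is the
   equivalent-circle diameter `2 sqrt(A/pi)`, sub-pixel accurate for a
   rasterized disc, and `px_per_cm = width_px / 2.47`.
3. **Contour.** Leaf pixels are hue-thresholded into a binary mask; a
   Gaussian blur (default sigma 1 px) smooths the mask *only for component
   selection*. Measurements come from the raw classified pixels of every
   raw component touching the selected object — this keeps the thin blade
   apex that the blur erodes — with interior holes filled, so fissures and
   pest damage never affect measured widths. Among competing components the
   largest is kept and the rest are counted in an attribute.
4. **Widths.** The leaf span is divided into `n_segments` equal segments
   and the width at each segment's centre column is the count of foreground
   pixels perpendicular to the travel axis (robust to serrated edges),
   converted by the calibration. Positions are measured from the tip,
   identified as the narrower end.

Numerical floor: a leaf rendered at `p` px/cm has widths quantized at
`1/p` cm, and blade regions narrower than one pixel are unobservable in
principle. At 20 px/cm (the accuracy tests' scale) shape parameters are
recovered within ±0.05 (`alpha`) and ±0.02 (`a`) end to end.

## The canopy light experiment

**Development.** Daily growing degree days
`max(0, (tmin + tmax)/2 - 8 °C)` accumulate; leaf rank `n` (and its
internode) appears when the total passes `n × 30 °Cd`, up to 17 ranks.
Organ size is the final dimension times the sigmoid
`1 / (1 + exp(-0.05 (t - 40)))` of its thermal age `t`; the sigmoid starts
at about 0.12, not 0, which is accepted as part of the stated expansion
model.

**Geometry.** Each blade is a chain of 100 parallelogram panels along a
midrib whose inclination tapers linearly from the insertion angle at the
base to the tip angle (default 75° to 0°). Panel widths follow the shape
function on the same `l`-grid as the area-coefficient sum, scaled by the
shape-adjusted width, which makes the mesh area equal to
`length² × 0.75 / LWRatio` to machine precision — identical across shapes
by construction. Internodes are 6-facet prisms (0.1 m × 0.01 m radius by
default). Consecutive leaves are rotated 160°; the canopy is 6 rows × 14
identical plants at 0.75 m × 0.15 m (9 plants/m²); reporting is restricted
to the central 2 × 4 plants to avoid border effects.

**Sky.** Direct sunlight follows the hourly solar course at latitude
48.714° N on day of year 180 (declination from the standard 23.45° sine
formula), each hour weighted by the sine of the solar elevation and the
direct total normalized to 0.8. Diffuse light comes from 72 sources — 6
elevation rings × 12 azimuths at band centres — with uniform sky radiance,
i.e. ring weights proportional to `sin(e) cos(e)`, normalized to the 0.2
diffuse fraction. Sources below 3° elevation are dropped.

**Transport.** Rays are launched through a jittered stratified grid on a
window perpendicular to each source, sized to the scene's bounding box;
per-source ray counts are proportional to delivered power so all rays carry
equal energy (weights are irradiance on the horizontal, so unit energy
arrives per m² of ground). Leaf interactions use reflectance 0.0923 and
transmittance 0.0127 with Lambertian scattering on the incident /opposite
side; the implementation uses weighted transport — each hit deposits the
absorbed share `(1 − ρ − τ)` of the path weight and the path continues with
the scattered share — which has the same expectation as terminating paths
by an absorb/reflect/transmit draw but much lower variance. Paths are
terminated at the reflection depth with the remaining weight tallied as
lost (never as absorbed), so interception is non-decreasing in depth;
per-ray RNG substreams make deeper runs exact continuations of shallower
ones. The ground is fully absorbing; energy balance
(absorbed + soil + escaped + lost = emitted) holds to machine precision by
construction. Ray–primitive intersection uses a median-split BVH whose
tallies are bit-identical to brute force.

**Reported quantity.** Canopy interception is the energy absorbed by the
central plants' leaves per m² of their ground area on the reporting day
(day 81 by default — the end-of-season daily fraction, not a season sum).
In a finite open-boundary scene a small amount of side-entering light makes
this an interception *index* rather than a strict fraction of overhead
irradiance; relative (shape-to-shape) comparisons, which are the
experiment's purpose, are unaffected. The 6×6 shape grid runs every
`(alpha, a)` combination in {0.5, …, 1.0} twice (Monte-Carlo standard error
from the pair) and divides each cell by the grid maximum. All cells of a
repetition share one tracer seed (common random numbers), so between-cell
differences are not swamped by independent noise.

**Desk-scale defaults.** 2×10⁵ rays at reflection depth 5 per run (the
reference protocol of 2×10⁸ rays at depth 30 is configurable); a full grid
is 36 × 2 runs, about two minutes of CPU. Cell-to-cell noise in the
relative table is below 0.01 at these settings.

## Architecture defaults and their calibration

The canopy experiment compares *shapes*; everything else is held constant.
Plant density, row geometry, phyllochron, expansion, optics and sky are
fixed at the values stated above. Per-rank leaf sizes and the leaf pose,
however, are not determined by any published number, and the shape-grid
outcome depends on them through a simple mechanism: blade area near the
insertion point sits on the steep part of the midrib and projects little
leaf area onto the ground, so base-heavy shapes (`a = 1`) intercept less
than mid-blade-heavy shapes (`a = 0.5`) — but only if the canopy is not so
dense that every shape intercepts nearly everything anyway.

With flat leaves (40° insertion) and a large canopy (LAI ≈ 5.7) the grid is
nearly flat (span ≈ 2%): the canopy saturates and shape cannot express
itself. The package therefore defaults to an erectophile canopy — insertion
75° tapering to a horizontal tip, per-rank lengths rising 0.15 m → 0.57 m
(rank 12) then easing to 0.48 m, length-to-width ratio 10, LAI ≈ 2.1 at
day 81 — under which the relative grid spans about 7% with its maximum in
the `a = 0.5` column and the `(1, 1)` cell near 0.93. These defaults were
chosen once, as the canopy configuration this experiment is meaningful
under, and are fully configurable (`plant_architecture()`).

## Known limitations

* The vision pipeline assumes one leaf per video, hue-separable foreground,
  and a constant belt speed; overlapping leaves and strong curl are out of
  scope (the physical device flattens leaves).
* The expansion-dependent variation of the area coefficient during leaf
  growth (values roughly 0.68–0.82 for `alpha = 0.7`) is noted but not
  modelled; `c` here always refers to the fully developed blade.
* The extended shape family with a third (beta) exponent is not
  implemented.
* Scene boundaries are open; reporting on the central plants reduces but
  does not eliminate finite-scene effects (see the interception index
  note above).
* Mixed-model inference on fitted parameters (cultivar/rank contrasts) is
  out of scope; the fit results are plain data for any downstream analysis.
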