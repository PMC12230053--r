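# leafshape

Camera-based quantification of maize (*Zea mays* L.) leaf shape, and
simulation of what leaf shape does to canopy light interception.

## The problem

Leaf width profiles drive both leaf area estimation and light capture in
functional-structural plant models (FSPMs), but measuring them by ruler is
slow: a handful of points per leaf. A conveyor-belt video recording — a
leaf passing under a camera together with a circular reference marker of
known diameter — yields hundreds of width measurements per leaf at almost
no extra cost. This package implements that measurement pipeline, the leaf
shape model it feeds, and a Monte-Carlo canopy light experiment built on
top, all exercised on synthetic inputs with known ground truth.

For whom: crop physiologists and phenotyping engineers who want dense leaf
width profiles from cheap video; FSPM modellers who want a transparent,
self-contained reference implementation of the shape-to-light chain.

## The model

Relative blade width at relative distance `l` from the tip follows the
two-parameter sine function

    w(l) = [ sin( pi * l / (2 a) ) ] ^ alpha ,   alpha > 0,  0.5 <= a <= 1

where `a` (the *ratio factor*) is the position of the maximum width and
`alpha` (the *shape factor*) controls blade narrowness. Integrating `w`
gives the leaf area coefficient `c` (fraction of the bounding rectangle
occupied by the blade; `c = 0.75` for the standard maize parameters
`alpha = 0.85`, `a = 0.70`), used both for leaf area (`LA = c·L·W`) and for
holding leaf area constant while comparing shapes:

    width_adj = length * (1 / LWRatio) * (0.75 / c)

The canopy experiment grows 6 rows x 14 identical plants (9 plants/m²) by
thermal time (phyllochron 30 °Cd over a base of 8 °C, sigmoid organ
expansion with k = 0.05, t_half = 40 °Cd), builds each blade from 100
width-varying parallelograms, and traces light from hourly direct sun
(latitude 48.714° N, day of year 180) plus a 72-source diffuse sky
(diffuse fraction 0.2) with leaf reflectance 0.0923 and transmittance
0.0127 through a BVH-accelerated Monte-Carlo ray tracer.

## Worked example

Generate a synthetic leaf video, measure it, and fit the shape function:

```r
library(leafshape)

truth <- shape_params(0.85, 0.70)
leaf  <- make_leaf_mask(synthetic_leaf_spec(50, 8, truth), px_per_cm = 10)
video <- render_video_frames(leaf, scene_spec(10, frame_width = 700,
                                              frame_height = 160,
                                              belt_speed = 16))
m <- process_video(video)
m
#> leaf_measurement: length 50.17 cm, max width 7.93 cm, 100 segments (9.97 px/cm)

fit <- fit_shape(normalize_profile(m$segments$position_cm, m$segments$width_cm))
fit
#> fit_result: alpha = 0.8288, a = 0.7071 | adj R2 = 0.9993, RMSE = 0.0105, n = 100

area_coefficient(truth)
#> area_coefficient: c = 0.7526 (riemann, 100 steps)
leaf_area(50, 8, area_coefficient(truth))   # cm^2
#> [1] 301.0349
```

The pipeline calibrated itself from the rendered marker (9.97 px/cm
detected vs 10 rendered), measured length and maximum width within ~1%,
and recovered the generating parameters (0.85, 0.70) as (0.83, 0.71) from
100 video-derived width samples; the area coefficient rounds to the
standard maize value 0.75.

Run the leaf-shape light experiment (about two minutes):

```r
grid <- run_shape_grid(seed = 1)   # 6x6 (alpha, a) grid, day 81, 2e5 rays x2
grid_table(grid)
#>       a
#> alpha  0.50 0.60 0.70 0.80 0.90 1.00
#>   0.50 1.00 0.98 0.97 0.96 0.96 0.96
#>   0.60 1.00 0.98 0.96 0.95 0.95 0.95
#>   0.70 1.00 0.97 0.96 0.95 0.95 0.94
#>   0.80 1.00 0.97 0.95 0.95 0.94 0.94
#>   0.90 1.00 0.97 0.95 0.94 0.94 0.94
#>   1.00 0.99 0.96 0.94 0.94 0.93 0.93
```

Each cell is the canopy light interception for that leaf shape (leaf area
held constant) relative to the grid maximum: base-heavy blades
(`a = 1.00`) intercept up to ~7% less light than mid-blade-heavy ones
(`a = 0.50`) under the default erectophile architecture.

A thin command-line wrapper over the same functions is installed at
`inst/exec/leafshape` (subcommands `coeff`, `fit`, `synth`, `measure`,
`grid`, `pipeline`).

## Package layout

| Where | What |
|---|---|
| `R/shape-model.R` | shape function, fitting, area coefficient, width identities |
| `R/synthetic-leaf.R`, `R/weather.R` | ground-truth leaf masks, conveyor videos, weather |
| `R/vision.R` | frame assembly, marker calibration, contours, segment widths |
| `R/development.R`, `R/canopy.R`, `R/light.R` | thermal time, plant/canopy geometry, sky + tracer |
| `src/tracer.cpp` | BVH Monte-Carlo ray tracer (Rcpp) |
| `R/io.R` | profile CSV / fit JSON readers-writers, pipeline |
| `vignettes/leafshape-methods.Rmd` | model, assumptions, design choices |
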