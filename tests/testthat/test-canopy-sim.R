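test_that("thermal time accumulates degree days and schedules leaves", {
  cfg <- development_config()
  w <- make_weather(40, tmin = 10, tmax = 20)
  tt <- thermal_time(w, cfg)
  expect_equal(tt$gdd[1], 7)  # (10+20)/2 - 8
  # floor at zero below the base temperature
  wc <- make_weather(5, tmin = 5, tmax = 5)
  expect_equal(thermal_time(wc, cfg)$gdd, rep(0, 5))
  # constant 8 degree-days/day: leaf 1 on day 4, leaf 10 on day 38
  w8 <- make_weather(81, tmin = 12, tmax = 20)
  tt8 <- thermal_time(w8, cfg)
  expect_equal(tt8$appearance_day[1], 4)
  expect_equal(tt8$appearance_day[10], 38)
  expect_error(thermal_time(w8[0, ], cfg), "non-empty")
})

test_that("sigmoid expansion has the right midpoint, start and limit", {
  expect_equal(expansion_fraction(40), 0.5)
  expect_equal(expansion_fraction(0), 1 / (1 + exp(2)), tolerance = 1e-12)
  expect_equal(expansion_fraction(1e6), 1)
  expect_true(all(diff(expansion_fraction(seq(0, 300, 10))) > 0))
})

test_that("leaf meshes hold area constant across shapes", {
  m1 <- build_leaf_mesh(1, 10, shape_params(0.5, 0.5))
  m2 <- build_leaf_mesh(1, 10, shape_params(1.0, 1.0))
  m3 <- build_leaf_mesh(1, 10, shape_params(0.85, 0.7))
  target <- 1 * 0.75 / 10
  for (m in list(m1, m2, m3))
    expect_equal(m$area, target, tolerance = 0.005)
  # geometric area of the primitives matches the analytic mesh area
  geom <- function(m) sum(sqrt(rowSums(
    cbind(m$prims[, 5] * m$prims[, 9] - m$prims[, 6] * m$prims[, 8],
          m$prims[, 6] * m$prims[, 7] - m$prims[, 4] * m$prims[, 9],
          m$prims[, 4] * m$prims[, 8] - m$prims[, 5] * m$prims[, 7])^2)))
  expect_equal(geom(m3), m3$area, tolerance = 1e-9)
  # widest panel: adjusted width at the ratio factor, counting from the tip
  cc <- area_coefficient(shape_params(0.85, 0.7))$c
  expect_equal(max(m3$widths), 0.1 * 0.75 / cc, tolerance = 1e-9)
  expect_equal(which.max(rev(m3$widths)), 70)  # panel 70 of 100 from the tip
  # rectangle limit: alpha -> 0 gives c -> 1 and one full-width panel
  r <- build_leaf_mesh(2, 10, shape_params(1e-9, 1), n_panels = 1)
  expect_equal(r$area, 2 * adjusted_width(2, 10, 1), tolerance = 1e-6)
})

test_that("canopy scene has the configured layout and development state", {
  w <- make_weather(81, tmin = 12, tmax = 20)
  sc <- build_canopy_scene(81, w)
  expect_equal(sc$n_plants, 6 * 14)
  expect_equal(sort(unique(sc$organ_table$rank)), 1:17)
  expect_equal(length(sc$report_organs), 8 * 17)  # central 2x4 plants
  expect_equal(sc$report_area_m2, 8 * 0.75 * 0.15)
  # all plants identical: per-plant leaf area equal
  la <- aggregate(area_m2 ~ plant, sc$organ_table[sc$organ_table$type == "leaf", ], sum)
  expect_lt(diff(range(la$area_m2)), 1e-12)
  # day before any leaf appears: internodes may exist but no leaf area
  sc3 <- build_canopy_scene(3, w)
  expect_false(any(sc3$organ_table$type == "leaf"))
  # early day: only the ranks that have appeared
  sc20 <- build_canopy_scene(20, w)
  expect_equal(max(sc20$organ_table$rank), findInterval(20 * 8 / 30, 1:17))
  expect_equal(1 / (0.75 * 0.15), 9, tolerance = 0.15)  # stated plant density
})

test_that("sky sources normalize weights and follow the solar geometry", {
  cfg <- light_config()
  ss <- sky_sources(cfg)
  expect_equal(sum(ss$weight), 1, tolerance = 1e-12)
  expect_equal(sum(ss$weight[ss$type == "diffuse"]), 0.2, tolerance = 1e-12)
  expect_equal(sum(ss$type == "diffuse"), 72)
  expect_true(all(ss$dz < 0))
  # standard declination oracle: noon elevation at lat 48.714, DOY 180
  decl <- 23.45 * sin(2 * pi * (284 + 180) / 365)
  noon <- 90 - 48.714 + decl
  expect_equal(max(ss$elevation[ss$type == "direct"]), noon, tolerance = 1.5)
  # direction vectors are unit length
  expect_equal(sqrt(ss$dx^2 + ss$dy^2 + ss$dz^2), rep(1, nrow(ss)),
               tolerance = 1e-9)
})

test_that("shape grid normalization and reporting contracts hold", {
  # a tiny 2x2 grid exercises the machinery end to end
  g <- run_shape_grid(alphas = c(0.6, 1), as = c(0.5, 1), day = 40,
                      light = light_config(n_rays = 2e4), n_reps = 2, seed = 5)
  expect_equal(nrow(g), 4)
  expect_true(all(g$relative > 0 & g$relative <= 1))
  expect_equal(max(g$relative), 1)
  expect_true(all(is.finite(g$se)))
  # leaf area identical across cells
  expect_lt(max(g$leaf_area) / min(g$leaf_area) - 1, 0.005)
  tb <- grid_table(g)
  expect_equal(dim(tb), c(2, 2))
})
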