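# Physics of the Monte-Carlo tracer on analytically tractable scenes.

test_that("energy is conserved exactly and fractions are sensible", {
  w <- make_weather(60, tmin = 12, tmax = 20)
  sc <- build_canopy_scene(60, w)
  lr <- trace_light(sc, light_config(n_rays = 5e4, seed = 3))
  balance <- sum(lr$organ_absorbed$absorbed) + lr$soil + lr$escaped +
    lr$truncated - lr$emitted
  expect_lt(abs(balance) / lr$emitted, 1e-9)
  expect_true(all(lr$organ_absorbed$absorbed >= 0))
  expect_gt(lr$canopy_interception, 0)
})

test_that("a single opaque leaf under a vertical beam absorbs everything", {
  sc <- flat_scene(square_prim(0.5, 0.5, 1, 10), 1L)
  lr <- trace_light(sc, light_config(n_rays = 1e4, leaf_reflectance = 0,
                                     leaf_transmittance = 0, seed = 1),
                    sources = vertical_beam)
  # black leaf covering the whole launch window: everything is absorbed
  expect_equal(lr$organ_absorbed$absorbed, lr$emitted, tolerance = 1e-9)
  expect_equal(lr$soil, 0)
})

test_that("two stacked leaves split absorption by the transmittance", {
  tau <- 0.0127
  # closely stacked so obliquely transmitted light cannot miss the lower leaf
  prims <- rbind(square_prim(0, 0, 1.0, 50), square_prim(0, 0, 0.95, 50))
  sc <- flat_scene(prims, c(1L, 2L))
  lr <- trace_light(sc, light_config(n_rays = 1e5, leaf_reflectance = 0,
                                     leaf_transmittance = tau,
                                     reflection_depth = 4, seed = 2),
                    sources = vertical_beam)
  ab <- lr$organ_absorbed$absorbed
  # bottom/top absorbed ratio equals the transmittance
  expect_equal(ab[2] / ab[1], tau, tolerance = 0.02)
})

test_that("random horizontal black leaves follow the Beer-Lambert limit", {
  # randomly placed squares approach the Poisson gap model; the dominant
  # uncertainty is the placement itself, so average over placements and
  # compare at three standard errors (plus a small floor for the residual
  # ray noise and boundary exchange of the finite arrangement)
  side <- 0.05
  trace_one <- function(lai, k) {
    n_sq <- round(lai * 1.2^2 / side^2)  # centres over the padded square
    set.seed(1000 + 17 * k + round(10 * lai))
    cx <- runif(n_sq, -0.1, 1.1); cy <- runif(n_sq, -0.1, 1.1)
    cz <- runif(n_sq, 0.2, 1.2)
    prims <- do.call(rbind, Map(square_prim, cx, cy, cz, side))
    central <- which(cx >= 0 & cx <= 1 & cy >= 0 & cy <= 1)
    sc <- flat_scene(prims, seq_len(n_sq), report_area = 1,
                     report_organs = central)
    trace_light(sc, light_config(n_rays = 2e4, leaf_reflectance = 0,
                                 leaf_transmittance = 0, seed = 20 + k),
                sources = vertical_beam)$canopy_interception
  }
  for (lai in c(0.5, 1, 2, 4)) {
    vals <- vapply(1:4, function(k) trace_one(lai, k), numeric(1))
    expected <- 1 - exp(-lai)
    se <- stats::sd(vals) / 2
    expect_lt(abs(mean(vals) - expected), 3 * se + 0.005)
  }
})

test_that("interception is monotone in reflection depth and in LAI", {
  w <- make_weather(60, tmin = 12, tmax = 20)
  sc <- build_canopy_scene(60, w)
  vals <- vapply(c(0L, 1L, 2L, 5L), function(d)
    trace_light(sc, light_config(n_rays = 5e4, reflection_depth = d,
                                 seed = 9))$canopy_interception, numeric(1))
  # per-ray substreams make deeper runs strict continuations: non-decreasing
  expect_true(all(diff(vals) >= 0))

  # black-leaf interception grows with LAI
  side <- 0.05
  ints <- vapply(c(0.5, 2), function(lai) {
    n_sq <- round(lai * 1.2^2 / side^2)
    set.seed(5)
    prims <- do.call(rbind, Map(square_prim, runif(n_sq, -0.1, 1.1),
                                runif(n_sq, -0.1, 1.1), runif(n_sq, 0.2, 1.2),
                                side))
    sc2 <- flat_scene(prims, seq_len(n_sq))
    trace_light(sc2, light_config(n_rays = 2e4, leaf_reflectance = 0,
                                  leaf_transmittance = 0, seed = 2),
                sources = vertical_beam)$canopy_interception
  }, numeric(1))
  expect_gt(ints[2], ints[1])
})

test_that("BVH traversal reproduces brute-force tallies exactly", {
  w <- make_weather(30, tmin = 12, tmax = 20)
  arch <- plant_architecture(final_leaf_number = 5, n_panels = 10)
  canopy <- canopy_config(rows = 2, plants_per_row = 3)
  sc <- build_canopy_scene(30, w, arch = arch, canopy = canopy)
  cfg <- light_config(n_rays = 1e4, seed = 11)
  a <- trace_light(sc, cfg)
  b <- trace_light(sc, cfg, brute_force = TRUE)
  expect_equal(a$organ_absorbed$absorbed, b$organ_absorbed$absorbed,
               tolerance = 1e-12)
  expect_equal(a$soil, b$soil, tolerance = 1e-12)
  expect_equal(a$escaped, b$escaped, tolerance = 1e-12)
})

test_that("runs are deterministic per seed and stable across seeds", {
  w <- make_weather(60, tmin = 12, tmax = 20)
  sc <- build_canopy_scene(60, w)
  cfg <- light_config(n_rays = 5e4, seed = 21)
  expect_identical(trace_light(sc, cfg)$canopy_interception,
                   trace_light(sc, cfg)$canopy_interception)
  # different seeds at high ray counts agree closely on canopy interception
  v1 <- trace_light(sc, light_config(n_rays = 4e6, seed = 1))$canopy_interception
  v2 <- trace_light(sc, light_config(n_rays = 4e6, seed = 2))$canopy_interception
  expect_lt(abs(v1 - v2), 0.005)
})

test_that("degenerate scenes are rejected", {
  sc <- flat_scene(square_prim(0, 0, 1, 1), 1L)
  sc$prims <- sc$prims[0, , drop = FALSE]
  sc$organs <- integer(0)
  expect_error(trace_light(sc, light_config(n_rays = 1e4)), "degenerate|empty")
})
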