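test_that("relative_width matches the sine shape family at anchor points", {
  p <- shape_params(0.85, 0.70)
  # tip and maximum
  expect_equal(relative_width(0, p), 0)
  expect_equal(relative_width(0.70, p), 1)
  expect_equal(relative_width(0.6, shape_params(2.3, 0.6)), 1)
  # direct high-precision evaluation of sin(pi/1.4)^0.85
  expect_equal(relative_width(1, p), sin(pi / 1.4)^0.85, tolerance = 1e-12)
  expect_equal(relative_width(1, p), 0.81123, tolerance = 1e-4)
})

test_that("relative_width stays in [0,1], peaks only at l = a, rises to it", {
  set.seed(11)
  for (k in 1:25) {
    p <- shape_params(runif(1, 0.1, 4.5), runif(1, 0.51, 1))
    l <- seq(0, 1, length.out = 401)
    w <- relative_width(l, p)
    expect_true(all(w >= 0 & w <= 1))
    # maximum attained only near l = a
    at_max <- l[w > 1 - 1e-9]
    expect_true(all(abs(at_max - p$a) < 0.01))
    # strictly increasing on [0, a]
    wl <- relative_width(seq(0, p$a, length.out = 100), p)
    expect_true(all(diff(wl) > 0))
  }
})

test_that("shape parameter domain is validated", {
  expect_error(shape_params(0, 0.7), "alpha")
  expect_error(shape_params(-1, 0.7), "alpha")
  expect_error(shape_params(0.85, 0.49), "a")
  expect_error(shape_params(0.85, 1.01), "a")
  # closed lower bound admits the elliptic blade
  expect_silent(shape_params(0.85, 0.5))
  expect_error(relative_width(1.5, shape_params(1, 1)), "l")
})

test_that("normalize_profile rescales by maxima and is idempotent", {
  pr <- normalize_profile(c(0, 25, 50), c(0, 4, 8))
  expect_equal(pr$rel_length, c(0, 0.5, 1))
  expect_equal(pr$rel_width, c(0, 0.5, 1))
  # hand arithmetic
  pr2 <- normalize_profile(c(0, 30, 60, 90), c(0, 6, 9, 3))
  expect_equal(pr2$rel_width, c(0, 6, 9, 3) / 9, tolerance = 1e-12)
  expect_equal(round(pr2$rel_width, 3), c(0, 0.667, 1, 0.333))
  # idempotence on already-normalized input
  pr3 <- normalize_profile(pr$rel_length, pr$rel_width)
  expect_equal(pr3$rel_length, pr$rel_length)
  expect_equal(pr3$rel_width, pr$rel_width)
  # degenerate input
  expect_error(normalize_profile(c(0, 1), c(0, 0)), "degenerate")
  expect_error(normalize_profile(c(1, 0.5), c(1, 1)), "increasing")
})

test_that("goodness_of_fit reproduces hand-computed values", {
  g <- goodness_of_fit(0:3, 0:3)
  expect_equal(g$adj_r2, 1)
  expect_equal(g$rmse, 0)
  g2 <- goodness_of_fit(c(0, 1, 2, 3), c(0.1, 0.9, 2.1, 2.9), n_params = 2)
  expect_equal(g2$rmse, 0.1, tolerance = 1e-12)
  # constant estimate: R^2 = 0 so the adjustment goes negative
  g3 <- goodness_of_fit(c(0, 1, 2, 3, 4), rep(2, 5), n_params = 2)
  expect_lt(g3$adj_r2, 0)
  expect_error(goodness_of_fit(1:3, 1:3, n_params = 2), "observations")
})

test_that("fit_shape recovers parameters from clean and noisy profiles", {
  truth <- shape_params(0.85, 0.70)
  l <- seq(0.02, 1, length.out = 50)
  w <- relative_width(l, truth)
  fit <- fit_shape(width_profile(l, w))
  expect_true(fit$converged)
  expect_equal(fit$params$alpha, 0.85, tolerance = 1e-6)
  expect_equal(fit$params$a, 0.70, tolerance = 1e-6)
  expect_equal(fit$adj_r2, 1, tolerance = 1e-9)

  set.seed(7)
  wn <- pmin(pmax(w + rnorm(50, 0, 0.02), 0), 1)
  fitn <- fit_shape(width_profile(l, wn))
  expect_true(fitn$converged)
  expect_lt(abs(fitn$params$alpha - 0.85), 0.05)
  expect_lt(abs(fitn$params$a - 0.70), 0.05)
})

test_that("degenerate constant-width profile pushes the fit to the bounds", {
  l <- seq(0.05, 1, length.out = 30)
  fit <- fit_shape(width_profile(l, rep(1, 30)))
  # brute-force grid over the box confirms no interior optimum: RSS decreases
  # toward alpha -> 0 and a -> 1, so the solution must sit on the boundary
  grid <- expand.grid(alpha = seq(0.05, 5, length.out = 40),
                      a = seq(0.51, 1, length.out = 40))
  rss <- mapply(function(al, av) sum((sin(pi * l / (2 * av))^al - 1)^2),
                grid$alpha, grid$a)
  best <- grid[which.min(rss), ]
  expect_lte(best$alpha, 0.06)           # smallest alpha in the grid wins
  expect_lt(fit$params$alpha, 0.01)      # fitter lands at the alpha bound
  expect_lte(fit$adj_r2, 0)
  expect_error(fit_shape(width_profile(l, rep(0, 30))), "zero")
})

test_that("fit_shape parameter recovery medians over 200 synthetic profiles", {
  set.seed(101)
  n <- 200
  err <- matrix(NA_real_, n, 2)
  for (i in seq_len(n)) {
    p <- shape_params(runif(1, 0.5, 1.2), runif(1, 0.55, 0.95))
    l <- sort(runif(30, 0.02, 1))
    w <- pmin(pmax(relative_width(l, p) + rnorm(30, 0, 0.02), 0), 1)
    f <- fit_shape(width_profile(l, w / max(w)))
    err[i, ] <- c(abs(f$params$alpha - p$alpha), abs(f$params$a - p$a))
  }
  expect_lte(median(err[, 1]), 0.05)
  expect_lte(median(err[, 2]), 0.02)
})

test_that("area_coefficient matches fixed values and closed forms", {
  # the commonly used maize coefficient for (0.85, 0.70)
  cc <- area_coefficient(shape_params(0.85, 0.70))
  expect_equal(round(cc$c, 2), 0.75)
  # closed-form integral of sin(pi l / 2) over [0,1] is 2/pi
  expect_lt(abs(area_coefficient(shape_params(1, 1))$c - 2 / pi), 0.005)
  # alpha -> 0: w -> 1 everywhere, c -> 1
  expect_equal(area_coefficient(shape_params(1e-6, 0.8))$c, 1, tolerance = 1e-4)
  expect_error(area_coefficient(shape_params(1, 1), steps = 5), "steps")
})

test_that("area_coefficient decreases in alpha and agrees with quadrature", {
  for (a in c(0.55, 0.7, 0.85, 1)) {
    cs <- vapply(seq(0.5, 1.2, by = 0.1),
                 function(al) area_coefficient(shape_params(al, a))$c, numeric(1))
    expect_true(all(diff(cs) < 0))
  }
  for (al in c(0.5, 0.8, 1.2)) for (a in c(0.55, 0.8, 1)) {
    exact <- integrate(function(l) sin(pi * l / (2 * a))^al, 0, 1,
                       rel.tol = 1e-10)$value
    expect_lt(abs(area_coefficient(shape_params(al, a))$c - exact), 0.005)
    expect_lt(abs(area_coefficient(shape_params(al, a),
                                   rule = "trapezoid")$c - exact), 0.005)
  }
})

test_that("adjusted width and leaf area identities hold", {
  expect_equal(adjusted_width(80, 10, 0.75), 8)
  expect_equal(adjusted_width(80, 10, 0.50), 12)
  # direction of the adjustment around the 0.75 reference
  expect_gt(adjusted_width(80, 10, 0.6), 8)
  expect_lt(adjusted_width(80, 10, 0.9), 8)
  expect_equal(leaf_area(100, 8, 0.75), 600)
  expect_equal(leaf_area(3, 2, 1), 6)  # rectangle limit
  expect_error(adjusted_width(-1, 10, 0.75), "positive")
  expect_error(leaf_area(10, 0, 0.75), "positive")

  # area invariance: leaf_area(length, adjusted_width(.), c) is independent
  # of the shape (exact algebraic identity)
  set.seed(3)
  for (k in 1:20) {
    p1 <- shape_params(runif(1, 0.3, 3), runif(1, 0.52, 1))
    p2 <- shape_params(runif(1, 0.3, 3), runif(1, 0.52, 1))
    c1 <- area_coefficient(p1); c2 <- area_coefficient(p2)
    a1 <- leaf_area(80, adjusted_width(80, 10, c1), c1)
    a2 <- leaf_area(80, adjusted_width(80, 10, c2), c2)
    expect_equal(a1, a2, tolerance = 1e-12)
    expect_equal(a1, 80^2 * 0.75 / 10, tolerance = 1e-12)
  }
})

test_that("mask pixel area of a rasterized leaf matches the area coefficient", {
  p <- shape_params(0.85, 0.70)
  msk <- make_leaf_mask(synthetic_leaf_spec(50, 8, p), 20)
  ratio <- sum(msk$mask) / (50 * 20 * 8 * 20)
  expect_equal(ratio, area_coefficient(p)$c, tolerance = 0.01)
})
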