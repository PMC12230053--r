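#' Leaf shape parameters
#'
#' Bundle and validate the two parameters of the sine leaf-shape function:
#' the shape factor `alpha` (exponent; larger values give narrower, more
#' lanceolate blades) and the ratio factor `a` (relative distance from the
#' tip at which maximum width occurs).
#'
#' @param alpha shape factor, `alpha > 0` (dimensionless).
#' @param a ratio factor, `0.5 <= a <= 1` (dimensionless). The boundary
#'   `a = 0.5` (an elliptic blade, widest at mid-length) is admitted for
#'   evaluating the shape family; [fit_shape()] keeps its lower bound open
#'   at 0.5.
#' @return An object of class `shape_params`.
#' @examples
#' shape_params(0.85, 0.70)
#' @export
shape_params <- function(alpha, a) {
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha) || alpha <= 0)
    stop("invalid shape parameters: 'alpha' must be a finite number > 0", call. = FALSE)
  if (!is.numeric(a) || length(a) != 1L || !is.finite(a) || a < 0.5 || a > 1)
    stop("invalid shape parameters: 'a' must satisfy 0.5 <= a <= 1", call. = FALSE)
  structure(list(alpha = as.numeric(alpha), a = as.numeric(a)), class = "shape_params")
}

#' @export
print.shape_params <- function(x, ...) {
  cat(sprintf("shape_params: alpha = %.4g, a = %.4g\n", x$alpha, x$a))
  invisible(x)
}

as_shape_params <- function(p) {
  if (inherits(p, "shape_params")) return(p)
  if (is.numeric(p) && length(p) == 2L) return(shape_params(p[[1L]], p[[2L]]))
  stop("expected a 'shape_params' object or a numeric (alpha, a) pair", call. = FALSE)
}

# Bare numeric kernel, no validation; used in fitting loops.
relative_width_num <- function(l, alpha, a) {
  s <- sin(pi * l / (2 * a))
  # guard tiny negative values from floating point when l slightly exceeds 2a
  pmax(s, 0)^alpha
}

#' Relative leaf width at a relative position along the blade
#'
#' The sine leaf-shape function
#' \deqn{w(l) = \sin\!\left(\frac{\pi l}{2 a}\right)^{\alpha}}
#' gives the leaf width relative to the maximum width at relative length
#' `l` measured from the leaf tip. The width is maximal (`w = 1`) exactly at
#' `l = a`. The argument of the sine is `pi * l / (2 * a)`: this placement is
#' what makes the maximum fall at `l = a`.
#'
#' @param l relative length from the tip, in `[0, 1]`; vectorised.
#' @param params a [shape_params()] object (or numeric `(alpha, a)` pair).
#' @return Relative width in `[0, 1]`, same length as `l`.
#' @examples
#' p <- shape_params(0.85, 0.70)
#' relative_width(c(0, 0.7, 1), p)
#' @export
relative_width <- function(l, params) {
  params <- as_shape_params(params)
  if (!is.numeric(l) || any(!is.finite(l)) || any(l < 0 | l > 1))
    stop("'l' must be numeric in [0, 1]", call. = FALSE)
  relative_width_num(l, params$alpha, params$a)
}

#' Build a relative width profile from physical measurements
#'
#' Normalizes positions and widths by their respective maxima, giving the
#' dimensionless profile the shape function is fitted to. Ordering of the
#' samples is preserved; positions must be strictly increasing (tip to base).
#' If several samples tie for the maximum width, the first occurrence defines
#' the normalizing value (they are equal, so the choice only fixes which index
#' is reported as the maximum).
#'
#' @param lengths positions along the midrib from the tip, cm, strictly
#'   increasing, max > 0.
#' @param widths widths perpendicular to the midrib, cm, max > 0.
#' @param cultivar,plant,rank,method optional identifiers carried as
#'   attributes.
#' @return A `width_profile`: data.frame with columns `rel_length`,
#'   `rel_width`.
#' @examples
#' normalize_profile(c(0, 25, 50), c(0, 4, 8))
#' @export
normalize_profile <- function(lengths, widths, cultivar = NA, plant = NA,
                              rank = NA, method = NA) {
  if (!is.numeric(lengths) || !is.numeric(widths) || length(lengths) == 0L ||
      length(lengths) != length(widths))
    stop("'lengths' and 'widths' must be non-empty numeric vectors of equal length",
         call. = FALSE)
  if (any(!is.finite(lengths)) || any(!is.finite(widths)) ||
      any(lengths < 0) || any(widths < 0))
    stop("'lengths' and 'widths' must be finite and nonnegative", call. = FALSE)
  if (any(diff(lengths) <= 0))
    stop("'lengths' must be strictly increasing (tip to base)", call. = FALSE)
  lmax <- max(lengths); wmax <- max(widths)
  if (lmax <= 0 || wmax <= 0)
    stop("degenerate leaf: maximum length and width must be positive", call. = FALSE)
  width_profile(lengths / lmax, widths / wmax,
                cultivar = cultivar, plant = plant, rank = rank, method = method)
}

#' Construct a width profile object
#'
#' @param rel_length relative lengths in `[0, 1]`, strictly increasing.
#' @param rel_width relative widths in `[0, 1]`.
#' @param cultivar,plant,rank,method optional identifiers.
#' @return A data.frame of class `width_profile`.
#' @export
width_profile <- function(rel_length, rel_width, cultivar = NA, plant = NA,
                          rank = NA, method = NA) {
  if (length(rel_length) == 0L || length(rel_length) != length(rel_width))
    stop("profile samples must be non-empty and of equal length", call. = FALSE)
  if (any(rel_length < 0 | rel_length > 1) || any(rel_width < 0 | rel_width > 1 + 1e-9))
    stop("relative lengths and widths must lie in [0, 1]", call. = FALSE)
  if (any(diff(rel_length) <= 0))
    stop("'rel_length' must be strictly increasing", call. = FALSE)
  structure(
    data.frame(rel_length = as.numeric(rel_length),
               rel_width = pmin(as.numeric(rel_width), 1)),
    class = c("width_profile", "data.frame"),
    ids = list(cultivar = cultivar, plant = plant, rank = rank, method = method))
}

#' Goodness of fit: adjusted R-squared and RMSE
#'
#' The coefficient of determination comes from regressing the observed values
#' on the estimated values (intercept included), after which the adjustment
#' `adj_r2 = 1 - (1 - R^2) (n - 1) / (n - n_params - 1)` accounts for the
#' number of model parameters. RMSE is the root mean squared difference
#' between observed and estimated.
#'
#' @param observed,estimated equal-length numeric vectors.
#' @param n_params number of fitted model parameters (2 for the shape
#'   function).
#' @return A list with `adj_r2` and `rmse`.
#' @examples
#' goodness_of_fit(0:3, c(0.1, 0.9, 2.1, 2.9), n_params = 2)
#' @export
goodness_of_fit <- function(observed, estimated, n_params = 2L) {
  n <- length(observed)
  if (n == 0L || n != length(estimated))
    stop("'observed' and 'estimated' must be non-empty and of equal length",
         call. = FALSE)
  if (n <= n_params + 1L)
    stop(sprintf("need more than n_params + 1 = %d observations, got %d",
                 n_params + 1L, n), call. = FALSE)
  rmse <- sqrt(mean((observed - estimated)^2))
  r2 <- if (stats::var(estimated) == 0 || stats::var(observed) == 0) {
    if (rmse == 0) 1 else 0
  } else {
    # a perfect fit triggers a harmless precision warning from summary.lm
    suppressWarnings(summary(stats::lm(observed ~ estimated))$r.squared)
  }
  adj_r2 <- 1 - (1 - r2) * (n - 1) / (n - n_params - 1)
  list(adj_r2 = adj_r2, rmse = rmse)
}

#' Fit the leaf shape function to a width profile
#'
#' Bounded Levenberg-Marquardt least squares (via [minpack.lm::nls.lm]) of the
#' sine shape function to relative width samples. If the first start fails to
#' converge, the fit is retried from the four corners of the parameter box
#' (moved slightly inside) and the converged solution with the lowest residual
#' sum of squares is kept.
#'
#' @param profile a [width_profile()] (or data.frame with `rel_length`,
#'   `rel_width`), at least 3 points.
#' @param init starting [shape_params()]; default `(0.85, 0.70)`, the fixed
#'   parameter values in common use for maize.
#' @param lower,upper parameter box `(alpha, a)`; defaults
#'   `alpha in (0, 5]`, `a in (0.5, 1]`.
#' @return A `fit_result` list: `params` ([shape_params()]), `adj_r2`,
#'   `rmse`, `n_points`, `converged`, `rss`.
#' @examples
#' p <- shape_params(0.85, 0.7)
#' l <- seq(0.02, 1, length.out = 50)
#' prof <- width_profile(l, relative_width(l, p))
#' fit_shape(prof)$params
#' @export
fit_shape <- function(profile, init = shape_params(0.85, 0.70),
                      lower = c(alpha = 1e-6, a = 0.5 + 1e-9),
                      upper = c(alpha = 5, a = 1)) {
  if (!is.data.frame(profile) || !all(c("rel_length", "rel_width") %in% names(profile)))
    stop("'profile' must have columns 'rel_length' and 'rel_width'", call. = FALSE)
  l <- profile$rel_length; w <- profile$rel_width
  n <- length(l)
  if (n < 3L) stop("need at least 3 points for a 2-parameter fit", call. = FALSE)
  if (any(w < 0 | w > 1 + 1e-9)) stop("widths must lie in [0, 1]", call. = FALSE)
  if (all(w == 0)) stop("all widths are zero: nothing to fit", call. = FALSE)
  init <- as_shape_params(init)

  resid_fun <- function(par) relative_width_num(l, par[1L], par[2L]) - w
  one_fit <- function(start) {
    tryCatch({
      res <- minpack.lm::nls.lm(
        par = start, fn = resid_fun, lower = unname(lower), upper = unname(upper),
        control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-12,
                                             ptol = 1e-12))
      list(par = res$par, rss = res$deviance, converged = res$info %in% 1:4)
    }, error = function(e) NULL)
  }

  starts <- list(c(init$alpha, init$a))
  fit <- one_fit(starts[[1L]])
  if (is.null(fit) || !fit$converged) {
    eps <- 1e-3
    corners <- list(
      c(lower[1L] + eps, lower[2L] + eps), c(lower[1L] + eps, upper[2L] - eps),
      c(upper[1L] - eps, lower[2L] + eps), c(upper[1L] - eps, upper[2L] - eps))
    cands <- Filter(Negate(is.null), c(list(fit), lapply(corners, one_fit)))
    conv <- Filter(function(f) isTRUE(f$converged), cands)
    pool <- if (length(conv)) conv else cands
    if (!length(pool)) stop("shape fit failed from all starting points", call. = FALSE)
    fit <- pool[[which.min(vapply(pool, `[[`, numeric(1), "rss"))]]
  }

  par <- fit$par
  est <- relative_width_num(l, par[1L], par[2L])
  gof <- goodness_of_fit(w, est, n_params = 2L)
  structure(list(
    params = shape_params(max(par[1L], 1e-6), min(max(par[2L], 0.5 + 1e-9), 1)),
    adj_r2 = gof$adj_r2, rmse = gof$rmse, n_points = n,
    converged = isTRUE(fit$converged), rss = fit$rss),
    class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("fit_result: alpha = %.4f, a = %.4f | adj R2 = %.4f, RMSE = %.4f, n = %d%s\n",
              x$params$alpha, x$params$a, x$adj_r2, x$rmse, x$n_points,
              if (x$converged) "" else " [NOT CONVERGED]"))
  invisible(x)
}

#' Leaf area coefficient
#'
#' Integrates the leaf shape function to obtain the fraction `c` of the
#' bounding rectangle (length x maximum width) occupied by the blade. The
#' default rule evaluates the function in `steps` steps at
#' `l = 1/steps, 2/steps, ..., 1` (for `steps = 100`: `0.01, 0.02, ..., 1.00`)
#' and averages; a trapezoidal rule over the same spacing is available as an
#' option.
#'
#' @param params a [shape_params()] object.
#' @param steps number of integration steps, `>= 10`; default 100.
#' @param rule `"riemann"` (default, fixed-grid sum) or `"trapezoid"`.
#' @return An `area_coefficient` object with fields `c`, `steps`, `rule`;
#'   `0 < c <= 1`.
#' @examples
#' area_coefficient(shape_params(0.85, 0.70))  # ~0.75
#' @export
area_coefficient <- function(params, steps = 100L, rule = c("riemann", "trapezoid")) {
  params <- as_shape_params(params)
  rule <- match.arg(rule)
  if (!is.numeric(steps) || steps < 10) stop("'steps' must be >= 10", call. = FALSE)
  steps <- as.integer(steps)
  cval <- if (rule == "riemann") {
    mean(relative_width_num(seq_len(steps) / steps, params$alpha, params$a))
  } else {
    l <- seq(0, 1, length.out = steps + 1L)
    w <- relative_width_num(l, params$alpha, params$a)
    (sum(w) - (w[1L] + w[steps + 1L]) / 2) / steps
  }
  structure(list(c = cval, steps = steps, rule = rule, params = params),
            class = "area_coefficient")
}

#' @export
print.area_coefficient <- function(x, ...) {
  cat(sprintf("area_coefficient: c = %.4f (%s, %d steps)\n", x$c, x$rule, x$steps))
  invisible(x)
}

coef_value <- function(c) {
  v <- if (inherits(c, "area_coefficient")) c$c else c
  if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0 || v > 1)
    stop("'c' must be an area coefficient in (0, 1]", call. = FALSE)
  v
}

#' Shape-adjusted leaf width
#'
#' Width that keeps leaf area constant across shapes:
#' `width_adj = length * (1 / LWRatio) * (0.75 / c)`. The reference value
#' 0.75 is the leaf area coefficient in common use for maize; consequently
#' the adjusted width increases for `c < 0.75` and decreases for `c > 0.75`,
#' and the resulting leaf area `length * width_adj * c` is independent of
#' shape.
#'
#' @param leaf_length leaf length, cm (or any length unit; output has the
#'   same unit).
#' @param lw_ratio length-to-width ratio (dimensionless, > 0).
#' @param c leaf area coefficient, an [area_coefficient()] object or a
#'   number in (0, 1].
#' @param reference reference coefficient; default 0.75.
#' @return Adjusted maximum leaf width in the units of `leaf_length`.
#' @examples
#' adjusted_width(80, 10, 0.75)  # 8
#' @export
adjusted_width <- function(leaf_length, lw_ratio, c, reference = 0.75) {
  if (any(!is.finite(leaf_length)) || any(leaf_length <= 0))
    stop("'leaf_length' must be positive", call. = FALSE)
  if (any(!is.finite(lw_ratio)) || any(lw_ratio <= 0))
    stop("'lw_ratio' must be positive", call. = FALSE)
  leaf_length * (1 / lw_ratio) * (reference / coef_value(c))
}

#' Leaf area from length, width and area coefficient
#'
#' `area = length * width * c`: the blade occupies fraction `c` of its
#' bounding rectangle.
#'
#' @param length leaf length (cm).
#' @param width maximum leaf width (cm).
#' @param c leaf area coefficient ([area_coefficient()] or number in (0, 1]).
#' @return Leaf area (cm^2).
#' @examples
#' leaf_area(100, 8, 0.75)  # 600
#' @export
leaf_area <- function(length, width, c) {
  if (any(!is.finite(length)) || any(length <= 0)) stop("'length' must be positive", call. = FALSE)
  if (any(!is.finite(width)) || any(width <= 0)) stop("'width' must be positive", call. = FALSE)
  length * width * coef_value(c)
}
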