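#' Light simulation configuration
#'
#' Monte-Carlo ray-tracing settings. The reference protocol uses 200 million
#' rays and a reflection depth of 30; the package defaults are scaled to
#' desk size (2e5 rays, depth 5) and both are freely configurable.
#'
#' @param n_rays number of rays per run; default 2e5, minimum 1e4.
#' @param reflection_depth maximum number of scattering events per path;
#'   paths still travelling at this depth are terminated (their remaining
#'   energy is tallied as lost, never as absorbed). Default 5.
#' @param diffuse_fraction fraction of incoming light that is diffuse;
#'   default 0.2.
#' @param n_elevation_rings,n_azimuths diffuse sky discretization: 6
#'   elevation arrays x 12 azimuths = 72 sources by default.
#' @param latitude site latitude, degrees; default 48.714.
#' @param day_of_year day of year for the solar course; default 180.
#' @param leaf_reflectance,leaf_transmittance scattering probabilities per
#'   hit; defaults 0.0923 and 0.0127; their sum must be < 1.
#' @param min_elevation direct-beam sources below this solar elevation
#'   (degrees) are dropped; default 3.
#' @param seed integer seed for the tracer RNG.
#' @return A `light_config` object.
#' @export
light_config <- function(n_rays = 2e5, reflection_depth = 5L,
                         diffuse_fraction = 0.2,
                         n_elevation_rings = 6L, n_azimuths = 12L,
                         latitude = 48.714, day_of_year = 180L,
                         leaf_reflectance = 0.0923, leaf_transmittance = 0.0127,
                         min_elevation = 3, seed = 1L) {
  stopifnot(n_rays >= 1e4, reflection_depth >= 0,
            diffuse_fraction >= 0, diffuse_fraction <= 1,
            leaf_reflectance >= 0, leaf_transmittance >= 0)
  if (leaf_reflectance + leaf_transmittance >= 1)
    stop("reflectance + transmittance must be < 1", call. = FALSE)
  structure(list(n_rays = as.integer(n_rays),
                 reflection_depth = as.integer(reflection_depth),
                 diffuse_fraction = diffuse_fraction,
                 n_elevation_rings = as.integer(n_elevation_rings),
                 n_azimuths = as.integer(n_azimuths),
                 latitude = latitude, day_of_year = as.integer(day_of_year),
                 leaf_reflectance = leaf_reflectance,
                 leaf_transmittance = leaf_transmittance,
                 min_elevation = min_elevation, seed = as.integer(seed)),
            class = "light_config")
}

solar_declination <- function(day_of_year) {
  23.45 * pi / 180 * sin(2 * pi * (284 + day_of_year) / 365)
}

#' Sky light sources: hourly direct sun plus discretized diffuse sky
#'
#' Direct sources follow the hourly diurnal solar course at the configured
#' latitude and day of year (declination from the standard 23.45 deg sine
#' formula, elevation/azimuth from the hour angle); each hour's weight is
#' proportional to the sine of the solar elevation, and direct weights are
#' normalized to `1 - diffuse_fraction`. Diffuse light comes from
#' `n_elevation_rings x n_azimuths` sources (default 6 x 12 = 72) at the
#' centres of equal-elevation bands; assuming a uniform-radiance sky, each
#' ring's weight is proportional to `sin(e) cos(e)` and diffuse weights are
#' normalized to `diffuse_fraction`. All weights together sum to 1 and are
#' expressed as irradiance on the horizontal.
#'
#' @param cfg a [light_config()].
#' @return A data.frame with columns `dx, dy, dz` (unit propagation
#'   direction, downward), `weight`, `type` ("direct"/"diffuse"),
#'   `elevation` (degrees).
#' @export
sky_sources <- function(cfg = light_config()) {
  lat <- cfg$latitude * pi / 180
  if (abs(cfg$latitude) >= 66)
    stop("latitude must be below the polar circle for an hourly day/night course",
         call. = FALSE)
  decl <- solar_declination(cfg$day_of_year)

  hours <- seq(0.5, 23.5, by = 1)
  H <- (hours - 12) * 15 * pi / 180
  sin_e <- sin(lat) * sin(decl) + cos(lat) * cos(decl) * cos(H)
  keep <- sin_e > sin(cfg$min_elevation * pi / 180)
  e <- asin(sin_e[keep]); Hk <- H[keep]
  # azimuth measured from north, positive eastward
  az <- atan2(-cos(decl) * sin(Hk),
              sin(decl) * cos(lat) - cos(decl) * sin(lat) * cos(Hk))
  sun <- cbind(cos(e) * sin(az), cos(e) * cos(az), sin(e))
  direct <- data.frame(dx = -sun[, 1L], dy = -sun[, 2L], dz = -sun[, 3L],
                       weight = sin(e), type = "direct",
                       elevation = e * 180 / pi)
  direct$weight <- direct$weight / sum(direct$weight) * (1 - cfg$diffuse_fraction)

  nb <- cfg$n_elevation_rings; na <- cfg$n_azimuths
  e_ring <- (seq_len(nb) - 0.5) / nb * pi / 2
  phi <- 2 * pi * (seq_len(na) - 0.5) / na
  ering <- rep(e_ring, each = na); phis <- rep(phi, times = nb)
  w <- rep(sin(e_ring) * cos(e_ring), each = na)
  diffuse <- data.frame(dx = -cos(ering) * sin(phis), dy = -cos(ering) * cos(phis),
                        dz = -sin(ering),
                        weight = w / sum(w) * cfg$diffuse_fraction,
                        type = "diffuse", elevation = ering * 180 / pi)
  if (cfg$diffuse_fraction >= 1) direct <- direct[0, ]
  if (cfg$diffuse_fraction <= 0) diffuse <- diffuse[0, ]
  rbind(direct, diffuse)
}

#' Trace light through a canopy scene
#'
#' Monte-Carlo ray tracing over parallelogram primitives. Rays are emitted
#' from each sky source through a launch window sized to cover the scene's
#' bounding box from that direction; per-source ray counts are proportional
#' to the energy each source delivers, so every ray carries (nearly) equal
#' energy. At each hit a ray is reflected (probability = leaf reflectance,
#' Lambertian, same side), transmitted (probability = leaf transmittance,
#' Lambertian, opposite side) or absorbed; paths reaching the reflection
#' depth are terminated and their energy tallied as lost. The ground is a
#' fully absorbing plane at z = 0. Weights are normalized so one unit of
#' energy arrives per m^2 of horizontal ground, hence canopy interception is
#' absorbed leaf energy of the reporting plants divided by the reporting
#' ground area.
#'
#' @param scene a `canopy_scene` from [build_canopy_scene()] (or a custom
#'   scene with `prims`, `organs`, `bbox`, `report_area_m2`,
#'   `report_organs`).
#' @param cfg a [light_config()].
#' @param sources optional data.frame overriding [sky_sources()] (columns
#'   `dx, dy, dz, weight`).
#' @param brute_force if TRUE, bypass the BVH and test every primitive per
#'   ray (contract check for small scenes).
#' @return A `light_result` list: `organ_absorbed` (data.frame: organ,
#'   absorbed energy), `by_rank`, `by_plant` (aggregates, when the scene has
#'   an organ table), `canopy_interception`, `soil`, `escaped`, `truncated`,
#'   `emitted`, `n_rays`.
#' @export
trace_light <- function(scene, cfg = light_config(), sources = NULL,
                        brute_force = FALSE) {
  if (!nrow(scene$prims)) stop("degenerate geometry: scene has no primitives",
                               call. = FALSE)
  if (is.null(sources)) sources <- sky_sources(cfg)
  if (!nrow(sources)) stop("no light sources", call. = FALSE)

  bb <- scene$bbox
  res <- trace_rays_cpp(scene$prims, as.integer(scene$organs),
                        as.matrix(sources[, c("dx", "dy", "dz")]),
                        sources$weight,
                        c(bb[["xmin"]], bb[["xmax"]], bb[["ymin"]], bb[["ymax"]],
                          bb[["zmin"]], bb[["zmax"]]),
                        as.integer(cfg$n_rays), as.integer(cfg$reflection_depth),
                        cfg$leaf_reflectance, cfg$leaf_transmittance,
                        as.integer(cfg$seed), isTRUE(brute_force))

  organ_absorbed <- data.frame(organ = seq_along(res$absorbed),
                               absorbed = res$absorbed)
  out <- list(organ_absorbed = organ_absorbed,
              soil = res$soil, escaped = res$escaped, truncated = res$truncated,
              emitted = res$emitted, n_rays = cfg$n_rays)

  if (!is.null(scene$organ_table)) {
    tab <- merge(scene$organ_table, organ_absorbed, by = "organ", all.x = TRUE)
    tab$absorbed[is.na(tab$absorbed)] <- 0
    leaf <- tab[tab$type == "leaf", ]
    out$by_rank <- stats::aggregate(absorbed ~ rank, data = leaf, sum)
    out$by_plant <- stats::aggregate(absorbed ~ plant, data = leaf, sum)
    out$organ_table <- tab
  }
  central <- organ_absorbed$absorbed[organ_absorbed$organ %in% scene$report_organs]
  out$canopy_interception <- sum(central) / scene$report_area_m2
  structure(out, class = "light_result")
}

#' @export
print.light_result <- function(x, ...) {
  cat(sprintf(
    "light_result: canopy interception %.4f | soil %.3f escaped %.3f lost %.4f (of %.3f emitted), %d rays\n",
    x$canopy_interception, x$soil, x$escaped, x$truncated, x$emitted, x$n_rays))
  invisible(x)
}

#' Run the leaf-shape grid light experiment
#'
#' Simulates canopy light interception for every combination of the shape
#' factor `alpha` and ratio factor `a` (default: 0.5 to 1.0 in steps of 0.1,
#' 36 cells), with identical plant architecture in every cell — leaf area is
#' held constant across shapes via the width adjustment — and normalizes
#' each cell by the grid maximum. Each cell is simulated `n_reps` times
#' (default 2) with derived seeds to estimate Monte-Carlo standard errors.
#'
#' @param alphas,as grid values; defaults `seq(0.5, 1, 0.1)`.
#' @param day reporting day (days after sowing); default 81.
#' @param weather a [make_weather()] series; default: constant 12/20 deg C
#'   days covering `day`.
#' @param arch,canopy,dev,light architecture / layout / development / light
#'   configurations.
#' @param n_reps Monte-Carlo repetitions per cell; default 2.
#' @param seed global seed; per-cell, per-rep tracer seeds are derived from
#'   it.
#' @param verbose print per-cell progress.
#' @return A `shape_grid` data.frame: `alpha`, `a`, `interception` (mean
#'   absolute interception), `se`, `relative` (cell / grid maximum),
#'   `leaf_area` (per-plant leaf area, m^2).
#' @export
run_shape_grid <- function(alphas = seq(0.5, 1, by = 0.1),
                           as = seq(0.5, 1, by = 0.1),
                           day = 81L, weather = NULL,
                           arch = plant_architecture(),
                           canopy = canopy_config(),
                           dev = development_config(),
                           light = light_config(),
                           n_reps = 2L, seed = 1L, verbose = FALSE) {
  if (is.null(weather)) weather <- make_weather(day, tmin = 12, tmax = 20)
  sources <- sky_sources(light)
  cells <- expand.grid(alpha = alphas, a = as)
  res <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    al <- cells$alpha[i]; av <- cells$a[i]
    scene <- tryCatch(
      build_canopy_scene(day, weather, arch, canopy, dev,
                         shape = shape_params(al, av)),
      error = function(e) stop(sprintf("grid cell (alpha=%.2f, a=%.2f): %s",
                                       al, av, conditionMessage(e)), call. = FALSE))
    vals <- vapply(seq_len(n_reps), function(r) {
      cfg <- light
      # common random numbers: every cell of a repetition shares one tracer
      # seed, so between-cell differences (the quantity of interest) are not
      # swamped by independent Monte-Carlo noise in each cell
      cfg$seed <- derive_seed(seed, sprintf("grid-rep%d", r))
      trace_light(scene, cfg, sources = sources)$canopy_interception
    }, numeric(1))
    res[[i]] <- data.frame(alpha = al, a = av,
                           interception = mean(vals),
                           se = if (n_reps > 1) stats::sd(vals) / sqrt(n_reps) else NA_real_,
                           leaf_area = scene$leaf_area_per_plant)
    if (verbose)
      message(sprintf("cell alpha=%.2f a=%.2f: interception %.4f", al, av, mean(vals)))
  }
  grid <- do.call(rbind, res)
  grid$relative <- grid$interception / max(grid$interception)
  structure(grid, class = c("shape_grid", "data.frame"))
}

#' Format a shape grid as an alpha-by-a table
#'
#' @param grid a `shape_grid` from [run_shape_grid()].
#' @param value which column to tabulate; default `"relative"`.
#' @param digits rounding; default 2 (the precision the relative table is
#'   usually reported at).
#' @return A matrix with alpha values as rows and a values as columns.
#' @export
grid_table <- function(grid, value = "relative", digits = 2) {
  al <- sort(unique(grid$alpha)); av <- sort(unique(grid$a))
  m <- matrix(NA_real_, length(al), length(av),
              dimnames = list(alpha = sprintf("%.2f", al), a = sprintf("%.2f", av)))
  for (i in seq_len(nrow(grid)))
    m[sprintf("%.2f", grid$alpha[i]), sprintf("%.2f", grid$a[i])] <-
      round(grid[[value]][i], digits)
  m
}
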