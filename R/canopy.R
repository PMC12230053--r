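#' Default per-rank final leaf lengths
#'
#' A smooth maize-like rank profile for a compact, erect-leaved hybrid:
#' lengths rise from 0.15 m at rank 1 to 0.57 m at rank 12, then ease back
#' to 0.48 m at the final rank (canopy LAI about 2.1 at 9 plants per m^2
#' when fully expanded). Used when no measured per-rank table is supplied;
#' together with the default erect insertion angle this canopy reproduces
#' the published relative light-interception pattern across leaf shapes.
#'
#' @param n_ranks number of leaf ranks.
#' @return Numeric vector of final leaf lengths, m.
#' @export
default_leaf_lengths <- function(n_ranks = 17L) {
  r <- seq_len(n_ranks)
  up <- 0.15 + (0.57 - 0.15) * (pmin(r, 12L) - 1) / 11
  down <- 0.57 - 0.09 * pmax(r - 12L, 0) / max(1L, n_ranks - 12L)
  ifelse(r <= 12L, up, down)
}

#' Plant architecture
#'
#' Per-rank dimensions and pose parameters shared by every plant in a
#' scene. All architectural traits except the leaf shape parameters are held
#' identical across shape treatments so that simulated differences arise
#' from shape alone.
#'
#' @param final_leaf_number number of leaf ranks; default 17.
#' @param leaf_length_m per-rank final leaf lengths, m; default
#'   [default_leaf_lengths()].
#' @param lw_ratio per-rank length-to-width ratio (scalar recycled); default
#'   10.
#' @param internode_length_m,internode_radius_m final internode dimensions;
#'   defaults 0.1 m and 0.01 m.
#' @param divergence_angle azimuthal angle between consecutive leaves,
#'   degrees; default 160.
#' @param insertion_angle midrib inclination above horizontal at the leaf
#'   base, degrees; default 75 (erectophile maize). The inclination tapers
#'   linearly to `tip_angle` at the tip, giving a parabola-like droop. The
#'   steep base makes blade area near the insertion point project little
#'   onto the ground, which is what differentiates base-heavy from
#'   mid-blade-heavy leaf shapes in light interception.
#' @param tip_angle midrib inclination at the tip, degrees; default 0.
#' @param n_panels parallelogram panels per leaf; default 100.
#' @return A `plant_architecture` object.
#' @export
plant_architecture <- function(final_leaf_number = 17L,
                               leaf_length_m = default_leaf_lengths(final_leaf_number),
                               lw_ratio = 10,
                               internode_length_m = 0.1,
                               internode_radius_m = 0.01,
                               divergence_angle = 160,
                               insertion_angle = 75, tip_angle = 0,
                               n_panels = 100L) {
  n <- as.integer(final_leaf_number)
  leaf_length_m <- rep_len(leaf_length_m, n)
  lw_ratio <- rep_len(lw_ratio, n)
  internode_length_m <- rep_len(internode_length_m, n)
  if (any(leaf_length_m <= 0) || any(lw_ratio <= 0) ||
      any(internode_length_m <= 0) || internode_radius_m <= 0)
    stop("architecture dimensions must be positive", call. = FALSE)
  structure(list(final_leaf_number = n, leaf_length_m = leaf_length_m,
                 lw_ratio = lw_ratio, internode_length_m = internode_length_m,
                 internode_radius_m = internode_radius_m,
                 divergence_angle = divergence_angle,
                 insertion_angle = insertion_angle, tip_angle = tip_angle,
                 n_panels = as.integer(n_panels)),
            class = "plant_architecture")
}

#' Canopy layout configuration
#'
#' @param rows number of rows; default 6.
#' @param plants_per_row plants per row; default 14.
#' @param row_spacing_m distance between rows, m; default 0.75.
#' @param plant_spacing_m distance within a row, m; default 0.15 (together
#'   with the row spacing this gives about 9 plants per m^2).
#' @param report_rows,report_plants indices of the central rows / plants
#'   used for reporting, to avoid border effects; defaults: the 2 central
#'   rows and 4 central positions.
#' @return A `canopy_config` object.
#' @export
canopy_config <- function(rows = 6L, plants_per_row = 14L,
                          row_spacing_m = 0.75, plant_spacing_m = 0.15,
                          report_rows = NULL, report_plants = NULL) {
  rows <- as.integer(rows); plants_per_row <- as.integer(plants_per_row)
  stopifnot(rows >= 1, plants_per_row >= 1, row_spacing_m > 0, plant_spacing_m > 0)
  if (is.null(report_rows))
    report_rows <- unique(pmax(1L, pmin(rows, rows %/% 2L + c(0L, 1L))))
  if (is.null(report_plants))
    report_plants <- unique(pmax(1L, pmin(plants_per_row,
                                          plants_per_row %/% 2L + (-1L):2L)))
  structure(list(rows = rows, plants_per_row = plants_per_row,
                 row_spacing_m = row_spacing_m, plant_spacing_m = plant_spacing_m,
                 density = 1 / (row_spacing_m * plant_spacing_m),
                 report_rows = report_rows, report_plants = report_plants),
            class = "canopy_config")
}

#' Build a leaf mesh of width-varying parallelograms
#'
#' The blade is a chain of `n_panels` parallelograms along the midrib. Panel
#' widths follow the shape function on the grid `l = 1, (n-1)/n, ..., 1/n`
#' from base to tip (the same grid as the area-coefficient integral), scaled
#' by the shape-adjusted maximum width, so the total mesh area equals
#' `length * adjusted_width * c` (= `length^2 * 0.75 / LWRatio`) to machine
#' precision and is identical across shapes. The midrib is inclined
#' `insertion_angle` above horizontal at the base, tapering linearly to
#' `tip_angle` at the tip.
#'
#' @param length_m leaf length, m.
#' @param lw_ratio length-to-width ratio.
#' @param shape a [shape_params()] object.
#' @param n_panels number of panels; default 100.
#' @param insertion_angle,tip_angle midrib inclination at base / tip,
#'   degrees.
#' @param azimuth leaf azimuth, degrees.
#' @param base xyz of the insertion point, m.
#' @return A list: `prims` (`n_panels` x 9 matrix: origin, edge1, edge2),
#'   `area` (total mesh area, m^2), `widths` (panel widths, base to tip).
#' @export
build_leaf_mesh <- function(length_m, lw_ratio, shape, n_panels = 100L,
                            insertion_angle = 75, tip_angle = 0,
                            azimuth = 0, base = c(0, 0, 0)) {
  shape <- as_shape_params(shape)
  stopifnot(length_m > 0, lw_ratio > 0, n_panels >= 1)
  n <- as.integer(n_panels)
  cc <- area_coefficient(shape, steps = max(10L, n))$c
  w_max <- adjusted_width(length_m, lw_ratio, cc)

  # segment k runs base -> tip; its width is evaluated at l = 1 - (k-1)/n,
  # the same grid {1/n ... 1} as the area-coefficient sum (reversed).
  k <- seq_len(n)
  l_grid <- 1 - (k - 1) / n
  widths <- w_max * relative_width_num(l_grid, shape$alpha, shape$a)

  ds <- length_m / n
  l_mid <- 1 - (k - 0.5) / n
  theta <- (tip_angle + (insertion_angle - tip_angle) * l_mid) * pi / 180
  phi <- azimuth * pi / 180
  dir_h <- c(cos(phi), sin(phi))
  # midrib points
  dx <- ds * cos(theta) * dir_h[1L]
  dy <- ds * cos(theta) * dir_h[2L]
  dz <- ds * sin(theta)
  px <- base[1L] + cumsum(c(0, dx))[k]
  py <- base[2L] + cumsum(c(0, dy))[k]
  pz <- base[3L] + cumsum(c(0, dz))[k]
  # width direction: horizontal, perpendicular to the azimuth
  wx <- -sin(phi); wy <- cos(phi)

  prims <- cbind(px - widths / 2 * wx, py - widths / 2 * wy, pz,
                 dx, dy, dz,
                 widths * wx, widths * wy, 0)
  colnames(prims) <- c("ox", "oy", "oz", "e1x", "e1y", "e1z", "e2x", "e2y", "e2z")
  # panels of exactly zero width (e.g. the base panel when a = 0.5) carry no
  # area and are dropped from the geometry
  list(prims = prims[widths > max(widths) * 1e-9, , drop = FALSE],
       area = sum(ds * widths), widths = widths)
}

# Tessellate a vertical cylinder into rectangular facets (an open prism).
cylinder_prims <- function(base, length_m, radius_m, n_facets = 6L) {
  phi <- 2 * pi * (seq_len(n_facets) - 1L) / n_facets
  x0 <- base[1L] + radius_m * cos(phi)
  y0 <- base[2L] + radius_m * sin(phi)
  x1 <- base[1L] + radius_m * cos(phi + 2 * pi / n_facets)
  y1 <- base[2L] + radius_m * sin(phi + 2 * pi / n_facets)
  cbind(x0, y0, base[3L],
        x1 - x0, y1 - y0, 0,
        0, 0, length_m)
}

new_canopy_scene <- function(prims, organs, report_area_m2, report_organs,
                             meta = list()) {
  stopifnot(is.matrix(prims), ncol(prims) == 9L, nrow(prims) == length(organs))
  if (nrow(prims) == 0L) {
    return(structure(c(list(prims = prims, organs = organs,
                            bbox = c(xmin = 0, xmax = 0, ymin = 0, ymax = 0,
                                     zmin = 0, zmax = 0),
                            report_area_m2 = report_area_m2,
                            report_organs = report_organs), meta),
                     class = "canopy_scene"))
  }
  bbox <- c(xmin = min(prims[, 1L] + pmin(0, prims[, 4L]) + pmin(0, prims[, 7L])),
            xmax = max(prims[, 1L] + pmax(0, prims[, 4L]) + pmax(0, prims[, 7L])),
            ymin = min(prims[, 2L] + pmin(0, prims[, 5L]) + pmin(0, prims[, 8L])),
            ymax = max(prims[, 2L] + pmax(0, prims[, 5L]) + pmax(0, prims[, 8L])),
            zmin = min(prims[, 3L] + pmin(0, prims[, 6L]) + pmin(0, prims[, 9L])),
            zmax = max(prims[, 3L] + pmax(0, prims[, 6L]) + pmax(0, prims[, 9L])))
  structure(c(list(prims = prims, organs = organs, bbox = bbox,
                   report_area_m2 = report_area_m2,
                   report_organs = report_organs), meta),
            class = "canopy_scene")
}

#' @export
print.canopy_scene <- function(x, ...) {
  cat(sprintf("canopy_scene: %d primitives, %d organs, reporting area %.3f m^2\n",
              nrow(x$prims), nrow(x$organ_table %||% data.frame()),
              x$report_area_m2))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build the canopy scene for a given day
#'
#' Places identical plants on the grid defined by the canopy configuration.
#' Organ sizes are their final dimensions scaled by the sigmoid expansion
#' fraction of the organ's thermal age; a leaf and its subtending internode
#' appear when cumulative thermal time passes the rank's phyllochron
#' threshold. Consecutive leaves are rotated by the divergence angle.
#' Reporting (light interception) is restricted to the central plants to
#' avoid border effects.
#'
#' @param day day index into the weather series (days after sowing).
#' @param weather a [make_weather()] series covering `day`.
#' @param arch a [plant_architecture()].
#' @param canopy a [canopy_config()].
#' @param dev a [development_config()].
#' @param shape a [shape_params()] used for every rank, or a list of one
#'   [shape_params()] per rank.
#' @return A `canopy_scene` with primitive matrix, per-primitive organ ids,
#'   an `organ_table` (organ id, plant, rank, type, area), and reporting
#'   metadata.
#' @export
build_canopy_scene <- function(day, weather, arch = plant_architecture(),
                               canopy = canopy_config(),
                               dev = development_config(),
                               shape = shape_params(0.85, 0.70)) {
  stopifnot(day >= 1, day <= nrow(weather))
  nr <- arch$final_leaf_number
  shapes <- if (inherits(shape, "shape_params")) rep(list(shape), nr)
            else lapply(shape, as_shape_params)
  if (length(shapes) != nr)
    stop(sprintf("need one shape per rank (%d), got %d", nr, length(shapes)),
         call. = FALSE)

  tt <- thermal_time(weather, dev)
  cum <- tt$cum_gdd[day]
  ranks <- which(!is.na(tt$appearance_day) & tt$appearance_day <= day)
  ranks <- ranks[ranks <= nr]  # the architecture caps the rank count
  age <- pmax(0, cum - seq_len(nr) * dev$phyllochron)
  frac <- expansion_fraction(age, dev)

  # one reference plant at the origin
  plant_prims <- list(); plant_oid <- list()
  organ_rows <- list()
  inode_len <- arch$internode_length_m * frac
  ins_height <- cumsum(inode_len)
  oid <- 0L
  for (r in ranks) {
    oid <- oid + 1L
    plant_prims[[length(plant_prims) + 1L]] <-
      cylinder_prims(c(0, 0, if (r > 1) ins_height[r - 1L] else 0),
                     inode_len[r], arch$internode_radius_m)
    plant_oid[[length(plant_oid) + 1L]] <- rep(oid, 6L)
    organ_rows[[oid]] <- data.frame(organ = oid, rank = r, type = "internode")

    oid <- oid + 1L
    mesh <- build_leaf_mesh(arch$leaf_length_m[r] * frac[r], arch$lw_ratio[r],
                            shapes[[r]], n_panels = arch$n_panels,
                            insertion_angle = arch$insertion_angle,
                            tip_angle = arch$tip_angle,
                            azimuth = (r - 1L) * arch$divergence_angle,
                            base = c(0, 0, ins_height[r]))
    plant_prims[[length(plant_prims) + 1L]] <- mesh$prims
    plant_oid[[length(plant_oid) + 1L]] <- rep(oid, nrow(mesh$prims))
    organ_rows[[oid]] <- data.frame(organ = oid, rank = r, type = "leaf",
                                    area_m2 = mesh$area)
  }
  if (length(plant_prims)) {
    ref <- do.call(rbind, plant_prims)
    ref_oid <- unlist(plant_oid)
    n_org <- oid
  } else {
    ref <- matrix(numeric(0), ncol = 9L)
    ref_oid <- integer(0)
    n_org <- 0L
  }

  # replicate across the grid; plants along x within a row, rows along y
  np <- canopy$rows * canopy$plants_per_row
  px <- (rep(seq_len(canopy$plants_per_row), times = canopy$rows) - 0.5) *
    canopy$plant_spacing_m
  py <- (rep(seq_len(canopy$rows), each = canopy$plants_per_row) - 0.5) *
    canopy$row_spacing_m
  plant_row <- rep(seq_len(canopy$rows), each = canopy$plants_per_row)
  plant_pos <- rep(seq_len(canopy$plants_per_row), times = canopy$rows)

  nref <- nrow(ref)
  prims <- ref[rep(seq_len(nref), times = np), , drop = FALSE]
  shiftx <- rep(px, each = nref); shifty <- rep(py, each = nref)
  prims[, 1L] <- prims[, 1L] + shiftx
  prims[, 2L] <- prims[, 2L] + shifty
  organ_ids <- rep(ref_oid, times = np) + rep((seq_len(np) - 1L) * n_org, each = nref)

  organ_table <- if (n_org > 0) {
    base_tab <- do.call(rbind, lapply(organ_rows, function(d) {
      if (!"area_m2" %in% names(d)) d$area_m2 <- NA_real_
      d
    }))
    tab <- base_tab[rep(seq_len(n_org), times = np), ]
    tab$organ <- tab$organ + rep((seq_len(np) - 1L) * n_org, each = n_org)
    tab$plant <- rep(seq_len(np), each = n_org)
    tab$row <- rep(plant_row, each = n_org)
    tab$pos <- rep(plant_pos, each = n_org)
    rownames(tab) <- NULL
    tab
  } else data.frame(organ = integer(0), rank = integer(0), type = character(0),
                    area_m2 = numeric(0), plant = integer(0), row = integer(0),
                    pos = integer(0))

  central <- organ_table$row %in% canopy$report_rows &
    organ_table$pos %in% canopy$report_plants
  report_organs <- organ_table$organ[central & organ_table$type == "leaf"]
  report_area <- length(canopy$report_rows) * length(canopy$report_plants) *
    canopy$row_spacing_m * canopy$plant_spacing_m

  new_canopy_scene(prims, organ_ids, report_area, report_organs,
                   meta = list(organ_table = organ_table, day = day,
                               n_plants = np, canopy = canopy, arch = arch,
                               dev = dev,
                               leaf_area_per_plant =
                                 sum(organ_table$area_m2[organ_table$plant == 1L],
                                     na.rm = TRUE)))
}
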