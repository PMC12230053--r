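#' Specification of a synthetic leaf
#'
#' Describes a ground-truth-known leaf whose silhouette follows the sine
#' shape function, optionally with interior defects (holes from pest or wind
#' damage) and edge noise.
#'
#' @param length_cm blade length, cm.
#' @param max_width_cm maximum blade width, cm; must be smaller than the
#'   length.
#' @param shape a [shape_params()] object.
#' @param defects list of defects, each a list with `position` (relative
#'   length from the tip, in (0,1)), `offset` (lateral position as a fraction
#'   of the local half-width, in (-1, 1)) and `radius_cm`. Defects must lie
#'   strictly inside the silhouette.
#' @param edge_noise_sd standard deviation of per-column edge jitter, px
#'   (applied at rasterization); default 0.
#' @param rank,cultivar optional identifiers.
#' @return A `synthetic_leaf_spec` object.
#' @export
synthetic_leaf_spec <- function(length_cm, max_width_cm, shape,
                                defects = list(), edge_noise_sd = 0,
                                rank = NA, cultivar = NA) {
  stopifnot(is.numeric(length_cm), length_cm > 0,
            is.numeric(max_width_cm), max_width_cm > 0,
            is.numeric(edge_noise_sd), edge_noise_sd >= 0)
  if (max_width_cm >= length_cm)
    stop("'max_width_cm' must be smaller than 'length_cm'", call. = FALSE)
  shape <- as_shape_params(shape)
  for (d in defects) {
    if (!all(c("position", "offset", "radius_cm") %in% names(d)))
      stop("each defect needs 'position', 'offset' and 'radius_cm'", call. = FALSE)
    if (d$position <= 0 || d$position >= 1 || abs(d$offset) >= 1 || d$radius_cm <= 0)
      stop("defect outside the silhouette interior", call. = FALSE)
    hw <- max_width_cm / 2 * relative_width_num(d$position, shape$alpha, shape$a)
    if (d$radius_cm >= hw * (1 - abs(d$offset)))
      stop("defect radius reaches the leaf edge; defects must be strictly interior",
           call. = FALSE)
  }
  structure(list(length_cm = length_cm, max_width_cm = max_width_cm,
                 shape = shape, defects = defects,
                 edge_noise_sd = edge_noise_sd, rank = rank, cultivar = cultivar),
            class = "synthetic_leaf_spec")
}

#' Rasterize a synthetic leaf into a binary mask with ground truth
#'
#' Draws the leaf silhouette column by column (column 1 = tip, last column =
#' base) symmetric about the midrib row. The ground-truth table records, for
#' every column, the continuous width implied by the shape function and the
#' pixel count actually rasterized. Interior defects are carved out after the
#' truth table is computed, so they change the mask area but never the
#' outer-width ground truth.
#'
#' @param spec a [synthetic_leaf_spec()].
#' @param px_per_cm rasterization scale; the maximum width must map to at
#'   least 8 px.
#' @param seed integer seed for edge noise (only used when
#'   `edge_noise_sd > 0`).
#' @return A `leaf_mask` list: `mask` (logical matrix, rows = vertical),
#'   `truth` (data.frame `column_px, rel_length, width_px, width_cm`),
#'   `spec`, `px_per_cm`.
#' @examples
#' lm <- make_leaf_mask(synthetic_leaf_spec(50, 8, shape_params(0.85, 0.7)), 4)
#' sum(lm$mask) / (ncol(lm$mask) * max(lm$truth$width_px))
#' @export
make_leaf_mask <- function(spec, px_per_cm, seed = 1L) {
  stopifnot(inherits(spec, "synthetic_leaf_spec"), px_per_cm > 0)
  wmax_px <- spec$max_width_cm * px_per_cm
  if (wmax_px < 8)
    stop(sprintf("resolution too coarse: max width maps to %.1f px (< 8 px)", wmax_px),
         call. = FALSE)
  nx <- max(3L, round(spec$length_cm * px_per_cm))
  ny <- 2L * ceiling(wmax_px / 2 + 3) + 1L
  cy <- (ny + 1L) %/% 2L

  x <- seq_len(nx)
  l <- (x - 0.5) / nx                      # relative length from tip at column centre
  half_cm <- spec$max_width_cm / 2 * relative_width_num(l, spec$shape$alpha, spec$shape$a)
  half_px <- half_cm * px_per_cm
  if (spec$edge_noise_sd > 0)
    half_px <- pmax(0, half_px + with_seed(seed, rnorm(nx, 0, spec$edge_noise_sd)))

  rows <- matrix(seq_len(ny), nrow = ny, ncol = nx)
  # the midrib row is drawn wherever the blade has any width: the apex of a
  # flattened leaf is visible to the camera even where the blade half-width
  # falls below one pixel
  draw_half <- ifelse(half_px > 0, pmax(half_px, 0.51), 0)
  mask <- abs(rows - cy) < rep(draw_half, each = ny)
  truth <- data.frame(column_px = x, rel_length = l,
                      width_px = colSums(mask),
                      width_cm = 2 * half_px / px_per_cm)

  for (d in spec$defects) {
    dc <- d$position * nx
    dr <- cy + d$offset * half_px[max(1L, min(nx, round(dc)))]
    rad <- d$radius_cm * px_per_cm
    cols <- matrix(seq_len(nx), nrow = ny, ncol = nx, byrow = TRUE)
    mask[(rows - dr)^2 + (cols - dc)^2 <= rad^2] <- FALSE
  }

  structure(list(mask = mask, truth = truth, spec = spec, px_per_cm = px_per_cm),
            class = "leaf_mask")
}

#' Conveyor-scene specification for synthetic video rendering
#'
#' Emulates the recording geometry of a belt-fed leaf-area meter with a
#' video camera: the leaf and a circular reference marker of known physical
#' diameter travel across the field of view at constant speed. Defaults
#' mirror the recording setup the pipeline targets (1920x1080 px, 60 fps,
#' 2.47 cm marker); tests use smaller frames for speed.
#'
#' @param px_per_cm rendering scale, px per cm.
#' @param frame_width,frame_height frame size in px; defaults 1920 x 1080.
#' @param fps frames per second; default 60.
#' @param belt_speed belt displacement, px per frame; `>= 1`.
#' @param marker_diameter_cm known marker diameter; default 2.47 cm.
#' @param background,leaf_color,marker_color RGB triplets in `[0,1]`. The
#'   leaf is a green hue and the marker a distinct greenish (teal) hue so the
#'   two are separable by hue thresholding.
#' @param noise_sd per-pixel Gaussian intensity noise; default 0.01.
#' @param seed integer seed for rendering noise.
#' @return A `scene_spec` object.
#' @export
scene_spec <- function(px_per_cm, frame_width = 1920L, frame_height = 1080L,
                       fps = 60, belt_speed = 4,
                       marker_diameter_cm = 2.47,
                       background = c(0.45, 0.42, 0.50),
                       leaf_color = c(0.20, 0.65, 0.20),
                       marker_color = c(0.10, 0.62, 0.55),
                       noise_sd = 0.01, seed = 1L) {
  stopifnot(px_per_cm > 0, frame_width >= 16, frame_height >= 16,
            fps > 0, marker_diameter_cm > 0, noise_sd >= 0)
  if (belt_speed < 1) stop("'belt_speed' must be >= 1 px per frame", call. = FALSE)
  structure(list(px_per_cm = px_per_cm, frame_width = as.integer(frame_width),
                 frame_height = as.integer(frame_height), fps = fps,
                 belt_speed = belt_speed, marker_diameter_cm = marker_diameter_cm,
                 background = background, leaf_color = leaf_color,
                 marker_color = marker_color, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "scene_spec")
}

#' Render conveyor-belt video frames of a synthetic leaf
#'
#' The leaf mask and a filled circular marker (diameter
#' `marker_diameter_cm * px_per_cm` px) are placed on a virtual belt, the
#' marker ahead of the leaf in the travel direction so it enters the field of
#' view first, and translated by `belt_speed` px per frame across the frame.
#' Rendering is deterministic for a fixed scene seed.
#'
#' @param leaf a `leaf_mask` from [make_leaf_mask()].
#' @param scene a [scene_spec()]; its `px_per_cm` must match the mask's.
#' @param n_frames number of frames; default: enough for the whole
#'   marker-plus-leaf train to cross the field of view.
#' @return A `leaf_video` list: `frames` (list of `[height, width, 3]`
#'   arrays), `offsets` (belt offset in px of each frame, ground truth),
#'   `scene`, `leaf`.
#' @export
render_video_frames <- function(leaf, scene, n_frames = NULL) {
  stopifnot(inherits(leaf, "leaf_mask"), inherits(scene, "scene_spec"))
  if (abs(leaf$px_per_cm - scene$px_per_cm) > 1e-9)
    stop("leaf mask and scene must use the same px_per_cm", call. = FALSE)
  H <- scene$frame_height; W <- scene$frame_width
  mask <- leaf$mask
  if (nrow(mask) > H) stop("leaf taller than the frame", call. = FALSE)
  if (max(colSums(mask)) > H) stop("leaf wider than the frame", call. = FALSE)

  mr <- scene$marker_diameter_cm * scene$px_per_cm / 2
  if (2 * mr + 2 > H) stop("marker taller than the frame", call. = FALSE)
  gap <- max(10, round(2 * mr))

  # Belt coordinates u: marker centre at u = -(mr+1); leaf base..tip behind it.
  marker_u <- -(mr + 1)
  leaf_u1 <- floor(marker_u - mr - gap)      # leaf tip column (tip leads)
  leaf_u0 <- leaf_u1 - ncol(mask) + 1L
  train_len <- -leaf_u0
  v <- scene$belt_speed
  if (is.null(n_frames)) n_frames <- ceiling((train_len + W) / v) + 1L

  cy <- (H + 1) / 2
  leaf_row0 <- round(cy - nrow(mask) / 2)
  yy <- matrix(seq_len(H), nrow = H, ncol = W)

  base_frame <- array(rep(scene$background, each = H * W), dim = c(H, W, 3))
  frames <- vector("list", n_frames)
  offsets <- numeric(n_frames)
  with_seed(scene$seed, {
    for (f in seq_len(n_frames)) {
      off <- (f - 1L) * v
      offsets[f] <- off
      fr <- base_frame
      # marker: circle centred at x = marker_u + off
      mcx <- marker_u + off
      if (mcx + mr >= 1 && mcx - mr <= W) {
        xx <- matrix(seq_len(W), nrow = H, ncol = W, byrow = TRUE)
        mm <- (xx - mcx)^2 + (yy - cy)^2 <= mr^2
        for (ch in 1:3) { pl <- fr[, , ch]; pl[mm] <- scene$marker_color[ch]; fr[, , ch] <- pl }
      }
      # leaf: paste mask columns visible in this frame (tip at leaf_u1 side)
      x_tip <- leaf_u1 + off
      x0 <- x_tip - ncol(mask) + 1L
      vis <- max(1L, ceiling(x0)):min(W, floor(x_tip))
      if (length(vis) && vis[1L] <= vis[length(vis)]) {
        mcols <- round(vis - x0 + 1L)
        sub <- mask[, mcols, drop = FALSE]
        ridx <- leaf_row0:(leaf_row0 + nrow(mask) - 1L)
        for (ch in 1:3) {
          pl <- fr[ridx, vis, ch]
          pl[sub] <- scene$leaf_color[ch]
          fr[ridx, vis, ch] <- pl
        }
      }
      if (scene$noise_sd > 0)
        fr <- pmin(pmax(fr + rnorm(length(fr), 0, scene$noise_sd), 0), 1)
      frames[[f]] <- fr
    }
  })
  structure(list(frames = frames, offsets = offsets, scene = scene, leaf = leaf),
            class = "leaf_video")
}

#' Sparse manual-style sampling of a ground-truth width table
#'
#' Emulates ruler measurements: `n_points` evenly spaced positions along the
#' midrib from the tip to the base, with the first point at the tip assigned
#' width 0. Widths at interior points are interpolated from the ground-truth
#' table. The result is normalized to a relative [width_profile()].
#'
#' @param truth a ground-truth table from [make_leaf_mask()] (`$truth`) or a
#'   `leaf_mask` object.
#' @param n_points number of sample points, between 6 and 12.
#' @param length_cm blade length; taken from the `leaf_mask` if one is given.
#' @return A sparse [width_profile()] (method id `"manual"`).
#' @export
sample_manual_points <- function(truth, n_points, length_cm = NULL) {
  if (inherits(truth, "leaf_mask")) {
    length_cm <- truth$spec$length_cm
    truth <- truth$truth
  }
  if (n_points < 6 || n_points > 12)
    stop("'n_points' must be between 6 and 12", call. = FALSE)
  if (is.null(length_cm)) stop("'length_cm' required with a bare truth table", call. = FALSE)
  pos <- seq(0, length_cm, length.out = n_points)
  w <- stats::approx(truth$rel_length * length_cm, truth$width_cm, xout = pos,
                     rule = 2)$y
  w[1L] <- 0                                  # tip measurement is zero by convention
  width_profile(pos / length_cm, w / max(w), method = "manual")
}
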