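#' Options for the vision pipeline
#'
#' Thresholds and preprocessing parameters for segmentation, marker
#' detection and contour extraction. Segmentation is by hue window into a
#' binary mask (the default path), optionally smoothed by a Gaussian blur
#' before labelling; all thresholds are configurable.
#'
#' @param leaf_hue,marker_hue hue windows in `[0, 1]` (HSV) classifying leaf
#'   and reference-marker pixels.
#' @param min_saturation minimum HSV saturation for a pixel to count as
#'   foreground.
#' @param blur_sigma Gaussian blur sd in px applied to the binary mask
#'   before labelling; 0 disables.
#' @param min_leaf_area,min_marker_area minimum object areas in px.
#' @param circularity_min minimum circularity (`4 A / (pi * D^2)` with `D`
#'   the larger bounding-box side; 1 for a disc) for a marker candidate.
#' @param max_shift maximum per-frame displacement considered during
#'   assembly, px; default 64.
#' @return A `vision_options` list.
#' @export
vision_options <- function(leaf_hue = c(0.26, 0.40), marker_hue = c(0.42, 0.56),
                           min_saturation = 0.25, blur_sigma = 1,
                           min_leaf_area = 100, min_marker_area = 25,
                           circularity_min = 0.85, max_shift = 64L) {
  structure(list(leaf_hue = leaf_hue, marker_hue = marker_hue,
                 min_saturation = min_saturation, blur_sigma = blur_sigma,
                 min_leaf_area = min_leaf_area, min_marker_area = min_marker_area,
                 circularity_min = circularity_min, max_shift = as.integer(max_shift)),
            class = "vision_options")
}

vision_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("vision stage '%s': %s", stage, conditionMessage(e)), call. = FALSE))
}

# Classify an RGB array [H, W, 3] into leaf / marker logical masks by hue.
classify_pixels <- function(frame, opts = vision_options()) {
  stopifnot(length(dim(frame)) == 3L, dim(frame)[3L] == 3L)
  H <- dim(frame)[1L]; W <- dim(frame)[2L]
  rgb <- rbind(as.vector(frame[, , 1L]), as.vector(frame[, , 2L]),
               as.vector(frame[, , 3L]))
  hsv <- grDevices::rgb2hsv(rgb, maxColorValue = 1)
  sat_ok <- hsv[2L, ] >= opts$min_saturation
  leaf <- matrix(sat_ok & hsv[1L, ] >= opts$leaf_hue[1L] & hsv[1L, ] <= opts$leaf_hue[2L],
                 nrow = H, ncol = W)
  marker <- matrix(sat_ok & hsv[1L, ] >= opts$marker_hue[1L] & hsv[1L, ] <= opts$marker_hue[2L],
                   nrow = H, ncol = W)
  list(leaf = leaf, marker = marker)
}

frames_from_input <- function(x) {
  if (inherits(x, "leaf_video")) return(x$frames)
  if (is.list(x) && length(x) && is.array(x[[1L]])) return(x)
  if (is.character(x) && length(x) == 1L && dir.exists(x)) {
    files <- sort(list.files(x, pattern = "\\.png$", full.names = TRUE))
    if (!length(files)) stop("no PNG frames found in ", x, call. = FALSE)
    if (!requireNamespace("png", quietly = TRUE))
      stop("reading PNG frames requires the 'png' package", call. = FALSE)
    return(lapply(files, function(f) {
      a <- png::readPNG(f)
      if (length(dim(a)) == 2L) a <- array(rep(a, 3L), dim = c(dim(a), 3L))
      a[, , 1:3, drop = FALSE]
    }))
  }
  stop("unsupported video input: expected a leaf_video, list of frames, or directory",
       call. = FALSE)
}

#' Assemble a full-size leaf image from moving-belt frames
#'
#' Estimates the per-frame belt displacement by 1-D cross-correlation of the
#' foreground column profiles of successive frames, then pastes every frame
#' into a common belt coordinate system so the composite contains the entire
#' leaf (and marker) exactly once. Travel direction is detected automatically
#' from the sign of the estimated displacement, so reversed frame order
#' assembles identically. A known belt speed can be supplied to skip
#' estimation.
#'
#' @param frames a `leaf_video`, list of RGB arrays, or directory of PNG
#'   frames.
#' @param belt_speed optional known displacement in px/frame (positive means
#'   objects move toward larger x).
#' @param opts [vision_options()].
#' @return Composite RGB array with attribute `offsets` (per-frame belt
#'   offsets used).
#' @export
assemble_leaf_image <- function(frames, belt_speed = NULL, opts = vision_options()) {
  frames <- frames_from_input(frames)
  n <- length(frames)
  if (n < 1L) stop("no frames", call. = FALSE)
  H <- dim(frames[[1L]])[1L]; W <- dim(frames[[1L]])[2L]
  for (f in frames)
    if (!identical(dim(f)[1:2], c(H, W)))
      stop("inconsistent frame sizes", call. = FALSE)
  if (n == 1L) {
    out <- frames[[1L]]; attr(out, "offsets") <- 0; return(out)
  }

  if (is.null(belt_speed)) {
    classified <- lapply(frames, classify_pixels, opts = opts)
    smax <- opts$max_shift
    xcorr_peak <- function(p1, p2) {
      shifts <- -smax:smax
      cc <- vapply(shifts, function(s) {
        if (s >= 0) sum(p1[seq_len(W - s)] * p2[seq_len(W - s) + s])
        else sum(p1[seq_len(W + s) - s] * p2[seq_len(W + s)])
      }, numeric(1))
      shifts[which.max(cc)]
    }
    # a frame pair is usable when its foreground is substantial and fully
    # inside the frame: objects clipped at a frame edge shift the
    # correlation maximum toward zero. The compact marker satisfies this for
    # most of its transit even when the leaf is longer than the frame, so
    # marker-only profiles are tried first.
    pair_est <- function(profiles, min_px) {
      est <- rep(NA_real_, n - 1L)
      for (i in seq_len(n - 1L)) {
        p1 <- profiles[[i]]; p2 <- profiles[[i + 1L]]
        if (sum(p1) < min_px || sum(p2) < min_px) next
        if (p1[1L] > 0 || p1[W] > 0 || p2[1L] > 0 || p2[W] > 0) next
        est[i] <- xcorr_peak(p1, p2)
      }
      est[!is.na(est)]
    }
    est <- pair_est(lapply(classified, function(cl) colSums(cl$marker)),
                    min_px = 30)
    if (length(est) < 3L)
      est <- c(est, pair_est(lapply(classified, function(cl)
        colSums(cl$leaf | cl$marker)), min_px = 50))
    if (!length(est))
      stop("displacement estimation failure: no overlapping foreground between frames",
           call. = FALSE)
    # the belt moves at constant speed; the median over usable pairs is
    # robust to the remaining outliers
    disp <- rep(stats::median(est), n - 1L)
  } else {
    disp <- rep(belt_speed, n - 1L)
  }
  offsets <- c(0, cumsum(disp))

  # belt coordinate of frame f, column x: u = x - offsets[f]
  u_min <- floor(1 - max(offsets)); u_max <- ceiling(W - min(offsets))
  cw <- u_max - u_min + 1L
  comp <- array(0, dim = c(H, cw, 3))
  for (f in seq_len(n)) {
    cols <- seq_len(W) - round(offsets[f]) - u_min + 1L
    comp[, cols, ] <- frames[[f]]
  }
  attr(comp, "offsets") <- offsets
  comp
}

label_features <- function(mask, min_area) {
  lab <- EBImage::bwlabel(mask + 0)
  nlab <- max(lab)
  if (nlab == 0L) return(NULL)
  feats <- lapply(seq_len(nlab), function(k) {
    idx <- which(lab == k, arr.ind = TRUE)
    area <- nrow(idx)
    if (area < min_area) return(NULL)
    list(label = k, area = area,
         row_range = range(idx[, 1L]), col_range = range(idx[, 2L]))
  })
  feats <- Filter(Negate(is.null), feats)
  if (!length(feats)) return(NULL)
  list(lab = lab, feats = feats)
}

#' Calibrate pixels to centimetres from the reference marker
#'
#' Detects the circular reference marker by hue and circularity, scanning
#' candidates from the bottom of the image upward, and computes
#' `px_per_cm = detected marker width (px) / known marker width (cm)`.
#'
#' @param image composite RGB array (from [assemble_leaf_image()]) or a
#'   single frame.
#' @param marker_cm known marker diameter in cm; default 2.47.
#' @param opts [vision_options()].
#' @return A `calibration_metric` list: `px_per_cm`, `marker_px`,
#'   `marker_cm`.
#' @export
calibrate_from_marker <- function(image, marker_cm = 2.47, opts = vision_options()) {
  vision_stage("calibrate", {
    cl <- classify_pixels(image, opts)
    lf <- label_features(cl$marker, opts$min_marker_area)
    if (is.null(lf))
      stop("no reference marker found: cannot calibrate (is the marker in view?)")
    # bottom-to-top scan: candidates ordered by lowest pixel first
    ord <- order(-vapply(lf$feats, function(f) f$row_range[2L], numeric(1)))
    for (f in lf$feats[ord]) {
      wbb <- diff(f$col_range) + 1
      hbb <- diff(f$row_range) + 1
      circularity <- 4 * f$area / (pi * max(wbb, hbb)^2)
      if (circularity >= opts$circularity_min) {
        # equivalent-circle diameter from the pixel area: sub-pixel accurate
        # for a rasterized disc, unlike the bounding-box extent
        wpx <- 2 * sqrt(f$area / pi)
        return(structure(list(px_per_cm = wpx / marker_cm, marker_px = wpx,
                              marker_cm = marker_cm),
                         class = "calibration_metric"))
      }
    }
    stop("no circular marker candidate passed the circularity threshold")
  })
}

#' @export
print.calibration_metric <- function(x, ...) {
  cat(sprintf("calibration: %.2f px (marker) / %.2f cm = %.3f px/cm\n",
              x$marker_px, x$marker_cm, x$px_per_cm))
  invisible(x)
}

#' Extract the outer contour of the leaf
#'
#' Segments leaf pixels by hue, optionally blurs the binary mask, keeps the
#' largest connected component above the area threshold (others are
#' reported via attribute `discarded`), fills interior holes so that
#' fissures and pest damage never affect the outer contour, and returns the
#' outer contour polygon together with the filled mask.
#'
#' @param image composite RGB array.
#' @param opts [vision_options()].
#' @return A `leaf_contour` list: `contour` (n x 2 matrix of x, y pixel
#'   coordinates), `mask` (filled logical matrix), `area` (filled px count).
#' @export
extract_leaf_contour <- function(image, opts = vision_options()) {
  vision_stage("contour", {
    cl <- classify_pixels(image, opts)
    m <- cl$leaf + 0
    if (opts$blur_sigma > 0)
      m <- (EBImage::gblur(m, sigma = opts$blur_sigma) > 0.5) + 0
    lf <- label_features(m > 0, opts$min_leaf_area)
    if (is.null(lf))
      stop("empty detection: no leaf object above the area threshold")
    areas <- vapply(lf$feats, `[[`, numeric(1), "area")
    keep <- lf$feats[[which.max(areas)]]
    # the blurred mask selects the leaf object; widths come from the raw
    # classified pixels of every raw component that touches it (this keeps
    # thin structures such as the blade apex, which the blur erodes, while
    # excluding detached noise specks), so the blur never biases widths
    lab_raw <- EBImage::bwlabel(cl$leaf + 0)
    touching <- setdiff(unique(lab_raw[lf$lab == keep$label]), 0L)
    sel <- matrix(lab_raw %in% touching, nrow(m), ncol(m))
    filled <- EBImage::fillHull(sel + 0) > 0
    oc <- EBImage::ocontour(filled + 0)
    contour <- oc[[which.max(vapply(oc, nrow, integer(1)))]]
    structure(list(contour = contour, mask = filled, area = sum(filled)),
              class = "leaf_contour",
              discarded = length(areas) - 1L)
  })
}

#' Measure leaf width per segment
#'
#' Divides the leaf span along the travel axis into `n_segments` equal
#' segments and measures, at each segment's centre column, the width as the
#' count of foreground pixels perpendicular to the travel axis (robust to
#' serrated edges), converted to cm by the calibration metric. Positions are
#' measured from the leaf tip, which is identified as the narrower end.
#'
#' @param leaf a `leaf_contour` (from [extract_leaf_contour()]) or a logical
#'   mask matrix.
#' @param calibration a `calibration_metric` from [calibrate_from_marker()].
#' @param n_segments number of segments, `>= 3`; default 100.
#' @return A data.frame with columns `index`, `position_cm` (strictly
#'   increasing from the tip), `width_cm`.
#' @export
measure_segments <- function(leaf, calibration, n_segments = 100L) {
  vision_stage("segments", {
    if (inherits(leaf, "leaf_contour")) leaf <- leaf$mask
    stopifnot(is.matrix(leaf))
    if (missing(calibration) || !inherits(calibration, "calibration_metric"))
      stop("calibration missing: run calibrate_from_marker() first")
    if (n_segments < 3L) stop("'n_segments' must be >= 3")
    ppc <- calibration$px_per_cm
    wcol <- colSums(leaf)
    occ <- which(wcol > 0)
    if (!length(occ)) stop("empty leaf mask")
    x0 <- occ[1L]; x1 <- occ[length(occ)]
    len_px <- x1 - x0 + 1L

    # tip = narrower end
    k <- max(3L, ceiling(0.05 * len_px))
    left_w <- mean(wcol[x0:min(x1, x0 + k - 1L)])
    right_w <- mean(wcol[max(x0, x1 - k + 1L):x1])
    tip_left <- left_w <= right_w

    centers <- x0 - 1 + (seq_len(n_segments) - 0.5) * len_px / n_segments
    width_px <- wcol[pmin(x1, pmax(x0, round(centers)))]
    pos_px <- if (tip_left) centers - (x0 - 1) else (x1 + 1) - centers
    df <- data.frame(index = seq_len(n_segments),
                     position_cm = pos_px / ppc,
                     width_cm = width_px / ppc)
    df <- df[order(df$position_cm), ]
    df$index <- seq_len(n_segments)
    rownames(df) <- NULL
    df
  })
}

leaf_measurement <- function(segments, calibration, ids = list()) {
  structure(list(segments = segments,
                 length_cm = diff(range(segments$position_cm)) +
                   segments$position_cm[1L] * 2,  # span + tip/base half-segments
                 max_width_cm = max(segments$width_cm),
                 n_segments = nrow(segments),
                 calibration = calibration, ids = ids),
            class = "leaf_measurement")
}

#' @export
print.leaf_measurement <- function(x, ...) {
  cat(sprintf("leaf_measurement: length %.2f cm, max width %.2f cm, %d segments (%.2f px/cm)\n",
              x$length_cm, x$max_width_cm, x$n_segments, x$calibration$px_per_cm))
  invisible(x)
}

#' Process a conveyor video end to end
#'
#' Chains frame assembly, marker calibration, contour extraction and
#' segment-wise width measurement: frames -> composite -> calibration ->
#' contour -> segments -> width-profile rows. Deterministic for fixed input
#' and options; stage failures propagate with the stage name.
#'
#' @param video a `leaf_video` object, list of RGB frames, or directory of
#'   PNG frames.
#' @param n_segments number of width measurements along the blade; default
#'   100.
#' @param belt_speed optional known belt speed (px/frame).
#' @param marker_cm known marker diameter, cm.
#' @param opts [vision_options()].
#' @param cultivar,plant,rank identifiers copied into the profile rows.
#' @return A `leaf_measurement` with an extra `profile` element: data.frame
#'   `cultivar, plant, rank, method, position_cm, width_cm`.
#' @export
process_video <- function(video, n_segments = 100L, belt_speed = NULL,
                          marker_cm = 2.47, opts = vision_options(),
                          cultivar = NA, plant = NA, rank = NA) {
  comp <- vision_stage("assemble", assemble_leaf_image(video, belt_speed, opts))
  calib <- calibrate_from_marker(comp, marker_cm, opts)
  contour <- extract_leaf_contour(comp, opts)
  segs <- measure_segments(contour, calib, n_segments)
  m <- leaf_measurement(segs, calib,
                        ids = list(cultivar = cultivar, plant = plant, rank = rank))
  m$profile <- data.frame(cultivar = cultivar, plant = plant, rank = rank,
                          method = "camera",
                          position_cm = segs$position_cm, width_cm = segs$width_cm)
  m
}
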