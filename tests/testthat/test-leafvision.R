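test_that("frame assembly reconstructs the full leaf from moving frames", {
  vid <- make_test_video()
  comp <- assemble_leaf_image(vid)
  # estimated displacement equals the true belt speed
  off <- attr(comp, "offsets")
  expect_equal(unique(round(diff(off), 6)), 10)
  # composite leaf length within 1% of the mask length
  cl <- leafshape:::classify_pixels(comp)
  span <- diff(range(which(colSums(cl$leaf) > 0))) + 1
  expect_equal(span, ncol(vid$leaf$mask), tolerance = 0.01)
  # a single frame assembles to itself
  one <- assemble_leaf_image(vid$frames[20])
  expect_equal(one[, , 1], vid$frames[[20]][, , 1])
})

test_that("reversed frame order assembles the same composite", {
  vid <- make_test_video()
  vid$scene$noise_sd <- 0  # regenerate noise-free for exact comparison
  msk <- vid$leaf
  scn <- vid$scene
  vid0 <- render_video_frames(msk, scn)
  fwd <- assemble_leaf_image(vid0$frames)
  rev <- assemble_leaf_image(rev(vid0$frames))
  cf <- leafshape:::classify_pixels(fwd); cr <- leafshape:::classify_pixels(rev)
  # identical leaf content (canvas extents may differ by a margin column)
  expect_equal(sum(cf$leaf), sum(cr$leaf))
  expect_equal(range(which(rowSums(cf$leaf) > 0)),
               range(which(rowSums(cr$leaf) > 0)))
})

test_that("marker calibration implements the px/cm ratio", {
  vid <- make_test_video(px_per_cm = 6)
  comp <- assemble_leaf_image(vid)
  calib <- calibrate_from_marker(comp)
  # the calibration metric is the detected width over the known width
  expect_equal(calib$px_per_cm, calib$marker_px / 2.47, tolerance = 1e-12)
  # and recovers the rendering scale to about a pixel on the marker
  expect_equal(calib$px_per_cm, 6, tolerance = 0.02)
  # a frame with no marker aborts with an actionable message
  blank <- array(0.4, dim = c(60, 80, 3))
  expect_error(calibrate_from_marker(blank), "marker")
})

test_that("contour extraction keeps the outer edge and drops interior holes", {
  vid <- make_test_video()
  comp <- assemble_leaf_image(vid)
  ct <- extract_leaf_contour(comp)
  expect_equal(ct$area, sum(vid$leaf$mask), tolerance = 0.01)

  vidh <- make_test_video(defects = list(list(position = 0.5, offset = 0,
                                              radius_cm = 1)))
  cth <- extract_leaf_contour(assemble_leaf_image(vidh))
  # the filled mask of the holed leaf equals the clean one
  expect_equal(cth$area, ct$area, tolerance = 0.005)
  expect_error(extract_leaf_contour(array(0.4, dim = c(60, 80, 3))),
               "empty detection")
})

test_that("segment widths match generator ground truth and count contracts", {
  vid <- make_test_video(px_per_cm = 6)
  m <- process_video(vid)
  expect_equal(nrow(m$segments), 100)
  expect_equal(m$n_segments, 100)
  ppc_true <- 6
  truth <- vid$leaf$truth
  got <- approx(m$segments$position_cm / m$length_cm, m$segments$width_cm,
                xout = truth$rel_length, rule = 2)$y
  tol_cm <- max(2 / ppc_true, 0.02 * max(truth$width_cm))
  expect_lt(stats::quantile(abs(got - truth$width_cm), 0.95), tol_cm)
  # max width and widest-position recovery
  expect_equal(m$max_width_cm, 8, tolerance = 0.04)
  # widths are pixel-quantized, so the maximum is a plateau; its centre
  # sits at the ratio factor
  px <- 1 / m$calibration$px_per_cm
  plateau <- m$segments$position_cm[m$segments$width_cm >= m$max_width_cm - px]
  expect_equal(mean(range(plateau)) / m$length_cm, 0.70, tolerance = 0.03)
  # coarse and fine segmentation agree on the maximum
  m10 <- process_video(vid, n_segments = 10)
  expect_equal(nrow(m10$segments), 10)
  expect_equal(m10$max_width_cm, m$max_width_cm, tolerance = 0.02)
  # missing calibration is an error
  ct <- extract_leaf_contour(assemble_leaf_image(vid))
  expect_error(measure_segments(ct, n_segments = 50), "calibration")
})

test_that("widths are invariant to interior defects and to the pixel scale", {
  clean <- process_video(make_test_video())
  holed <- process_video(make_test_video(
    defects = list(list(position = 0.5, offset = 0, radius_cm = 1))))
  expect_equal(holed$segments$width_cm, clean$segments$width_cm,
               tolerance = 1e-12)

  # scale equivariance: cm outputs agree across rendering scales
  hi <- process_video(make_test_video(px_per_cm = 12, frame_width = 900,
                                      frame_height = 220, belt_speed = 20))
  expect_equal(hi$max_width_cm, clean$max_width_cm, tolerance = 0.02)
  expect_equal(hi$length_cm, clean$length_cm, tolerance = 0.02)
  w_lo <- approx(clean$segments$position_cm / clean$length_cm,
                 clean$segments$width_cm, xout = seq(0.05, 0.95, 0.05))$y
  w_hi <- approx(hi$segments$position_cm / hi$length_cm,
                 hi$segments$width_cm, xout = seq(0.05, 0.95, 0.05))$y
  # agreement at the pixel-quantization floor of the coarser rendering
  expect_lt(stats::quantile(abs(w_hi - w_lo), 0.9) / max(w_lo), 0.02)
})

test_that("end-to-end: fitted shape parameters recover the generator values", {
  vid <- make_test_video(alpha = 0.85, a = 0.70, px_per_cm = 10,
                         frame_width = 700, frame_height = 160,
                         belt_speed = 16)
  m <- process_video(vid)
  prof <- normalize_profile(m$segments$position_cm, m$segments$width_cm)
  fit <- fit_shape(prof)
  expect_lt(abs(fit$params$alpha - 0.85), 0.05)
  expect_lt(abs(fit$params$a - 0.70), 0.02)
})
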