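# Shared fixtures, all generated in code.

# A small conveyor video of one synthetic leaf; modest resolution keeps the
# vision tests fast while staying above the pipeline's accuracy floor.
make_test_video <- function(alpha = 0.85, a = 0.70, length_cm = 50,
                            width_cm = 8, px_per_cm = 6, frame_width = 480,
                            frame_height = 120, belt_speed = 10, seed = 2,
                            defects = list(), edge_noise_sd = 0) {
  spec <- synthetic_leaf_spec(length_cm, width_cm, shape_params(alpha, a),
                              defects = defects, edge_noise_sd = edge_noise_sd)
  mask <- make_leaf_mask(spec, px_per_cm, seed = seed)
  scn <- scene_spec(px_per_cm, frame_width = frame_width,
                    frame_height = frame_height, belt_speed = belt_speed,
                    seed = seed)
  render_video_frames(mask, scn)
}

# A single horizontal square leaf as one parallelogram primitive.
square_prim <- function(cx, cy, z, side) {
  matrix(c(cx - side / 2, cy - side / 2, z, side, 0, 0, 0, side, 0), nrow = 1)
}

# Minimal custom scene for tracer physics tests.
flat_scene <- function(prims, organs, report_area = 1,
                       report_organs = unique(organs)) {
  leafshape:::new_canopy_scene(prims, organs, report_area, report_organs)
}

vertical_beam <- data.frame(dx = 0, dy = 0, dz = -1, weight = 1)
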