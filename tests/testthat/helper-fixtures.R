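# Shared fixtures: a quarter-scale scene geometry for fast unit tests
# (full-size scenes are exercised in the acceptance suite).

small_scene_cfg <- function(...) {
  scene_config(image_size = c(180, 320), ...)
}

small_shape <- function(...) {
  calf_shape_params(body_length_px = 155, body_width_px = 75,
                    dorsal_height_mm = 420, head_length_px = 40,
                    head_width_px = 35, head_offset_px = 12, ...)
}

# segmentation parameters rescaled to the quarter-scale geometry
small_seg_params <- function(cfg = small_scene_cfg(), ...) {
  segmentation_params(area_bounds = c(5000, 12500), bbox_bounds = c(60, 230),
                      template = make_template_contour(cfg, small_shape()),
                      ...)
}

random_mask <- function(h = 15, w = 15, p = 0.4) {
  matrix(rbinom(h * w, 1, p), h, w)
}
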