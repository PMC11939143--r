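# Synthetic dorsal depth-scene generator.
#
# Emulates the recording geometry the pipeline was designed for: a depth
# camera mounted 1.51 m above the floor looking straight down at a calf
# standing at a milk feeder, frames of 720 x 1280 px. The calf is modelled
# as a smooth dorsal surface (body ellipse plus head ellipse with a
# flattened-dome height profile), the floor as a noisy plane at camera
# height. The colorized render derives from depth through a monotone
# depth->hue ramp, so the fixed hue threshold used by the segmenter
# separates floor from calf by construction. Defects mimicking the field
# failure modes (overexposed white coat patches -> missing depth; fence
# bars in view) are injected only after the ground-truth mask is captured,
# so truth is defect-free by construction.

#' Scene generation settings
#'
#' @param image_size integer (H, W) in px.
#' @param camera_height_mm camera height above floor, mm.
#' @param floor_noise_sd_mm depth noise SD on floor pixels, mm.
#' @param calf_noise_sd_mm depth noise SD on calf pixels, mm.
#' @param fence_bars number of vertical fence bars rendered in front of the
#'   floor (0 disables them).
#' @param fence_width_px bar width, px.
#' @param fence_height_mm bar height above the floor, mm.
#' @param overexposure_fraction fraction of calf pixels whose depth reading
#'   is destroyed (set to 0/black), emulating overexposure of white coat.
#' @param overexposure_patch_px radius (px) of the roughly circular missing
#'   patches; overexposure wipes out contiguous coat patches, not isolated
#'   pixels, so it cannot be undone by morphological closing.
#' @param hue_floor,hue_slope,hue_max monotone depth-to-hue ramp on the
#'   0-179 hue scale: hue = min(hue_max, hue_floor + hue_slope * height_mm),
#'   where height = camera_height - depth. The floor sits near `hue_floor`
#'   (default 30) and the calf's back well above the segmentation threshold
#'   of 60.
#' @return an object of class `scene_config`.
#' @export
scene_config <- function(image_size = c(720, 1280), camera_height_mm = 1510,
                         floor_noise_sd_mm = 4, calf_noise_sd_mm = 2,
                         fence_bars = 0, fence_width_px = 18,
                         fence_height_mm = 350,
                         overexposure_fraction = 0, overexposure_patch_px = 45,
                         hue_floor = 30, hue_slope = 0.6, hue_max = 170) {
  if (overexposure_fraction < 0 || overexposure_fraction > 1)
    stop_validation("overexposure_fraction must be in [0, 1]")
  if (hue_slope <= 0 || hue_floor < 0 || hue_max <= hue_floor)
    stop_validation("hue ramp must be monotone increasing in height")
  if (floor_noise_sd_mm < 0 || calf_noise_sd_mm < 0)
    stop_validation("noise SDs must be >= 0")
  structure(list(image_size = as.integer(image_size),
                 camera_height_mm = camera_height_mm,
                 floor_noise_sd_mm = floor_noise_sd_mm,
                 calf_noise_sd_mm = calf_noise_sd_mm,
                 fence_bars = fence_bars, fence_width_px = fence_width_px,
                 fence_height_mm = fence_height_mm,
                 overexposure_fraction = overexposure_fraction,
                 overexposure_patch_px = overexposure_patch_px,
                 hue_floor = hue_floor, hue_slope = hue_slope,
                 hue_max = hue_max),
            class = "scene_config")
}

#' Calf body-shape settings
#'
#' Body and head are ellipses; the dorsal height profile is a flattened dome,
#' `height = peak * (1 - d^8)^(1/2)` with `d` the normalized elliptical
#' radius, so the back is nearly flat and falls off steeply at the flanks.
#' Defaults give a contour of roughly 160,000 px with a bounding box of
#' about 300 x 750 px, inside the segmenter's acceptance bounds.
#'
#' @param body_length_px,body_width_px full ellipse axes of the trunk, px.
#' @param dorsal_height_mm peak height of the back above the floor, mm.
#' @param head_length_px,head_width_px full axes of the head ellipse, px.
#' @param head_offset_px gap between trunk-ellipse end and head centre, px.
#' @param posture_angle_deg rotation of the whole animal in the image plane.
#' @param center 0-based (row, col) of the trunk centre; NULL = image centre.
#' @return an object of class `calf_shape_params`.
#' @export
calf_shape_params <- function(body_length_px = 620, body_width_px = 300,
                              dorsal_height_mm = 420,
                              head_length_px = 160, head_width_px = 140,
                              head_offset_px = 50,
                              posture_angle_deg = 0, center = NULL) {
  if (body_length_px <= 0 || body_width_px <= 0 || dorsal_height_mm <= 0)
    stop_validation("calf dimensions must be positive")
  structure(list(body_length_px = body_length_px, body_width_px = body_width_px,
                 dorsal_height_mm = dorsal_height_mm,
                 head_length_px = head_length_px, head_width_px = head_width_px,
                 head_offset_px = head_offset_px,
                 posture_angle_deg = posture_angle_deg, center = center),
            class = "calf_shape_params")
}

# dorsal height (mm) and mask over the full pixel grid; returns list(mask,
# height) where mask is strict interior of the union of the two ellipses
calf_height_field <- function(shape, H, W) {
  ctr <- if (is.null(shape$center)) c((H - 1) / 2, (W - 1) / 2) else shape$center
  th <- shape$posture_angle_deg * pi / 180
  r <- matrix(0:(H - 1), H, W) - ctr[1]
  c_ <- matrix(0:(W - 1), H, W, byrow = TRUE) - ctr[2]
  u <- c_ * cos(th) + r * sin(th)    # along body axis
  v <- -c_ * sin(th) + r * cos(th)   # across body
  aL <- shape$body_length_px / 2; aW <- shape$body_width_px / 2
  d2b <- (u / aL)^2 + (v / aW)^2
  hb <- ifelse(d2b < 1, shape$dorsal_height_mm * sqrt(pmax(0, 1 - d2b^4)), 0)
  hcL <- shape$head_length_px / 2; hcW <- shape$head_width_px / 2
  u0 <- aL + shape$head_offset_px
  d2h <- ((u - u0) / hcL)^2 + (v / hcW)^2
  hh <- ifelse(d2h < 1, 0.55 * shape$dorsal_height_mm * sqrt(pmax(0, 1 - d2h^4)), 0)
  height <- pmax(hb, hh)
  list(mask = (height > 0) + 0L, height = height)
}

depth_to_hue <- function(depth, config) {
  height <- pmax(config$camera_height_mm - depth, 0)
  hue <- pmin(config$hue_max, config$hue_floor + config$hue_slope * height)
  hue[depth == 0] <- 0  # missing readings render black
  hue
}

# 0..179 hue -> RGB lookup (full saturation/value), OpenCV-style hue scale
hue_to_rgb_lut <- function() {
  grDevices::col2rgb(grDevices::hsv(h = (0:179) / 180, s = 1, v = 1))
}

#' Render one synthetic depth scene with its ground-truth mask
#'
#' Floor pixels get depth ~ camera height plus noise; calf pixels get
#' `camera height - dorsal height` plus noise. The ground-truth mask is
#' captured before defects (overexposure, fence bars) are injected. The
#' color render maps depth through the config's hue ramp; missing-depth
#' pixels render black. Deterministic for a fixed seed.
#'
#' @param shape [calf_shape_params()].
#' @param config [scene_config()].
#' @param seed integer seed.
#' @param frame_id,calf_id,capture_date provenance carried on the scene.
#' @return list with elements `scene` ([depth_scene()]) and `mask`
#'   (integer {0,1} ground-truth matrix).
#' @export
render_scene <- function(shape, config = scene_config(), seed = 1,
                         frame_id = "synthetic", calf_id = NA_character_,
                         capture_date = NA_character_) {
  H <- config$image_size[1]; W <- config$image_size[2]
  hf <- calf_height_field(shape, H, W)
  if (sum(hf$mask) == 0) stop_validation("calf shape renders no pixels")
  idx <- which(hf$mask == 1L, arr.ind = TRUE)
  if (min(idx) < 1 || max(idx[, 1]) > H || max(idx[, 2]) > W ||
      any(idx[, 1] %in% c(1L, H)) || any(idx[, 2] %in% c(1L, W)))
    stop_validation("calf shape exceeds image bounds")
  with_seed(seed, {
    depth <- matrix(config$camera_height_mm +
                      rnorm(H * W, 0, config$floor_noise_sd_mm), H, W)
    cidx <- which(hf$mask == 1L)
    depth[cidx] <- config$camera_height_mm - hf$height[cidx] +
      rnorm(length(cidx), 0, config$calf_noise_sd_mm)
    depth <- pmax(depth, 0)
    truth <- hf$mask
    # -- defect injection (ground truth stays defect-free) --
    if (config$fence_bars > 0) {
      at <- round(seq(1, W - config$fence_width_px,
                      length.out = config$fence_bars + 2))[-c(1, config$fence_bars + 2)]
      for (cc in at)
        depth[, cc:(cc + config$fence_width_px - 1)] <-
          config$camera_height_mm - config$fence_height_mm
    }
    if (config$overexposure_fraction > 0) {
      target <- round(config$overexposure_fraction * length(cidx))
      coords <- which(hf$mask == 1L, arr.ind = TRUE)
      alive <- rep(TRUE, nrow(coords))
      rp <- config$overexposure_patch_px
      killed <- 0L
      while (killed < target && any(alive)) {
        ctr <- coords[sample(which(alive), 1), ]
        d2 <- (coords[, 1] - ctr[1])^2 + (coords[, 2] - ctr[2])^2
        hit <- which(alive & d2 <= rp^2)
        hit <- hit[order(d2[hit])]
        hit <- hit[seq_len(min(length(hit), target - killed))]
        depth[coords[hit, , drop = FALSE]] <- 0
        alive[hit] <- FALSE
        killed <- killed + length(hit)
      }
    }
    hue <- depth_to_hue(depth, config)
    lut <- hue_to_rgb_lut()
    hq <- pmin(179L, pmax(0L, as.integer(round(hue))))
    color <- array(0L, dim = c(H, W, 3))
    miss <- which(depth == 0)
    for (ch in 1:3) {
      plane <- matrix(lut[ch, hq + 1L], H, W)
      plane[miss] <- 0L   # missing readings render black
      color[, , ch] <- plane
    }
    list(scene = depth_scene(depth, color, frame_id = frame_id,
                             calf_id = calf_id, capture_date = capture_date,
                             camera_height_mm = config$camera_height_mm),
         mask = truth)
  })
}

#' Canonical calf template contour
#'
#' The idealized defect-free calf outline used by the segmenter's shape
#' filter. Rendered deterministically from the default shape parameters at
#' the config's scene geometry.
#'
#' @param config [scene_config()].
#' @param shape [calf_shape_params()]; the default is the canonical calf.
#' @return a [as_calf_contour()] object.
#' @export
make_template_contour <- function(config = scene_config(),
                                  shape = calf_shape_params()) {
  hf <- calf_height_field(shape, config$image_size[1], config$image_size[2])
  idx <- which(hf$mask == 1L, arr.ind = TRUE)
  rr <- range(idx[, 1]); cc <- range(idx[, 2])
  sub <- hf$mask[rr[1]:rr[2], cc[1]:cc[2], drop = FALSE]
  as_calf_contour(sub, offset = c(rr[1] - 1L, cc[1] - 1L))
}
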