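test_that("hue extraction follows the HSV definition on the 0-179 scale", {
  red <- array(0L, c(4, 5, 3)); red[, , 1] <- 255L
  s <- depth_scene(matrix(1000, 4, 5), red)
  expect_equal(hue_channel(s), matrix(0, 4, 5))

  teal <- array(0L, c(3, 3, 3)); teal[, , 2] <- 255L; teal[, , 3] <- 255L
  s2 <- depth_scene(matrix(1000, 3, 3), teal)
  expect_equal(hue_channel(s2), matrix(90, 3, 3))  # 180 deg -> 90

  expect_error(hue_channel(depth_scene(matrix(1000, 3, 3))), "color")
})

test_that("synthetic scenes separate floor and calf hue across the threshold", {
  s <- render_scene(small_shape(), small_scene_cfg(), seed = 4)
  hue <- hue_channel(s$scene)
  core <- EBImage::erode(s$mask, EBImage::makeBrush(9, "disc")) == 1
  expect_true(all(hue[core] > 60))
  floor_px <- s$mask == 0 & s$scene$depth > 0
  expect_true(all(hue[floor_px] < 60))
})

test_that("binarize sends equality to background and is monotone in threshold", {
  expect_equal(binarize(matrix(61), 60), matrix(1L))
  expect_equal(binarize(matrix(60), 60), matrix(0L))
  expect_equal(binarize(matrix(0, 3, 3), 60), matrix(0L, 3, 3))

  set.seed(1)
  hue <- matrix(runif(400, 0, 179), 20, 20)
  for (th in c(20, 60, 100)) {
    lo <- binarize(hue, th); hi <- binarize(hue, th + 15)
    expect_true(all(hi <= lo))  # raising the threshold never adds foreground
  }
})

test_that("mask cleanup closes holes and removes specks, and stays local", {
  m <- matrix(0L, 60, 60); m[10:50, 10:50] <- 1L
  m[30:32, 30:32] <- 0L                     # interior hole
  m[3, 3] <- 1L                             # isolated speck
  cleaned <- clean_mask(m, segmentation_params())
  expect_equal(cleaned[31, 31], 1L)
  expect_equal(cleaned[3, 3], 0L)
  expect_equal(clean_mask(matrix(0L, 10, 10)), matrix(0L, 10, 10))

  # oracle check on the speck-removal path: opening kills sub-kernel islands
  m2 <- matrix(0L, 20, 20); m2[5, 5] <- 1L; m2[10:15, 10:15] <- 1L
  expect_equal(sum(oracle_dilate3(oracle_erode3(m2))), sum(m2) - 1)

  # closure never grows foreground beyond the dilation radius of the input
  set.seed(2)
  for (i in 1:5) {
    m3 <- matrix(rbinom(900, 1, 0.3), 30, 30)
    grown <- m3
    for (k in 1:3) grown <- oracle_dilate3(grown)  # radius-2 disc < 3 steps
    expect_true(all(clean_mask(m3, segmentation_params()) <= grown))
  }
})

test_that("shape score is zero on identity, scale-invariant, large for bars", {
  tpl <- make_template_contour(small_scene_cfg(), small_shape())
  expect_equal(shape_score(tpl, tpl), 0)

  # ellipse vs its 2x copy
  e1 <- outer(seq(-1, 1, length.out = 61), seq(-1, 1, length.out = 91),
              function(r, c) (r^2 + c^2 <= 1) + 0L)
  e2 <- outer(seq(-1, 1, length.out = 121), seq(-1, 1, length.out = 181),
              function(r, c) (r^2 + c^2 <= 1) + 0L)
  expect_lt(shape_score(e1, e2), 0.02)

  bar <- matrix(1L, 10, 900)
  expect_gt(shape_score(bar, make_template_contour()), 0.8)

  expect_equal(shape_score(matrix(0L, 5, 5), tpl), Inf)
})

test_that("candidate selection applies shape, area and bbox filters in order", {
  rect <- function(h, w) as_calf_contour(matrix(1L, h, w))
  tpl <- rect(100, 160)
  p <- segmentation_params(area_bounds = c(10000, 20000),
                           bbox_bounds = c(50, 250),
                           shape_score_max = 0.5, template = tpl)
  good <- rect(100, 160)   # area 16000, bbox 100x160
  res <- select_target(list(good), p)
  expect_equal(res$status, "success")
  expect_equal(res$contour$area_px, 16000)

  expect_equal(select_target(list(), p)$status, "no_contours")

  small <- rect(70, 112)   # right shape, area 7840 below bounds
  expect_equal(select_target(list(small), p)$status, "failed_area")

  thin <- rect(10, 600)    # fails the shape filter first
  expect_equal(select_target(list(thin), p)$status, "no_match")

  wide <- rect(45, 300)    # aspect passes shape? no - use permissive shape cap
  p2 <- segmentation_params(area_bounds = c(10000, 20000),
                            bbox_bounds = c(50, 250),
                            shape_score_max = 100, template = tpl)
  expect_equal(select_target(list(wide), p2)$status, "failed_bbox")

  # among several survivors the largest area wins
  res2 <- select_target(list(rect(100, 120), rect(100, 160)), p2)
  expect_equal(res2$contour$area_px, 16000)
})

test_that("full segmentation succeeds on clean scenes and is deterministic", {
  s <- render_scene(small_shape(), small_scene_cfg(), seed = 6)
  p <- small_seg_params()
  r1 <- segment_scene(s$scene, p)
  r2 <- segment_scene(s$scene, p)
  expect_equal(r1$status, "success")
  expect_identical(r1$mask, r2$mask)
  expect_gt(mask_iou(r1$mask, s$mask), 0.99)
})

test_that("scenes without a calf yield a failure status, not an error", {
  cfg <- small_scene_cfg(floor_noise_sd_mm = 0)
  H <- cfg$image_size[1]; W <- cfg$image_size[2]
  depth <- matrix(cfg$camera_height_mm, H, W)
  hue <- calfdepth:::depth_to_hue(depth, cfg)
  lut <- calfdepth:::hue_to_rgb_lut()
  hq <- pmin(179L, pmax(0L, as.integer(round(hue))))
  color <- array(0L, c(H, W, 3))
  for (ch in 1:3) color[, , ch] <- matrix(lut[ch, hq + 1L], H, W)
  res <- segment_scene(depth_scene(depth, color), small_seg_params())
  expect_true(res$status %in% c("no_contours", "no_match"))
})

test_that("segment_batch reports per-frame status and IoU", {
  scenes <- lapply(1:2, function(i)
    render_scene(small_shape(), small_scene_cfg(), seed = i,
                 frame_id = sprintf("f%02d", i)))
  tab <- segment_batch(scenes, small_seg_params())
  expect_equal(tab$status, rep("success", 2))
  expect_true(all(tab$iou > 0.99))
  expect_true(all(c("area_px", "bbox_w", "bbox_l", "shape_score") %in% names(tab)))
})
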