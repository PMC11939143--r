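# Rule-based calf segmentation of colorized depth scenes:
#   hue extraction -> binary threshold -> morphological cleanup ->
#   contour extraction -> candidate filtering (shape, area, bounding box).
#
# The hue scale is 0-179 throughout (half-degrees, the convention under
# which the default threshold of 60 is meaningful). Failure is a
# first-class outcome: a scene where no candidate survives the filters
# yields a status, not an error.

#' Segmentation parameters
#'
#' Defaults encode the tuned field configuration: hue threshold 60,
#' candidate contour area within 80,000-200,000 px, both bounding-box sides
#' within 300-900 px, template shape-match score at most 0.8 (0 = identical
#' shapes, smaller = more similar).
#'
#' @param hue_threshold hue cut on the 0-179 scale; pixels strictly above
#'   it become foreground.
#' @param area_bounds (lo, hi) accepted filled-contour area, px.
#' @param bbox_bounds (lo, hi) accepted bounding-box side lengths, px;
#'   applied to both width and length.
#' @param shape_score_max maximum accepted [shape_score()] vs the template.
#' @param template template contour ([make_template_contour()] by default,
#'   built lazily when NULL).
#' @param closing_kernel_px,opening_kernel_px odd positive brush diameters
#'   for the closing (hole-filling) and opening (denoising) steps.
#' @return an object of class `segmentation_params`.
#' @export
segmentation_params <- function(hue_threshold = 60,
                                area_bounds = c(80000, 200000),
                                bbox_bounds = c(300, 900),
                                shape_score_max = 0.8,
                                template = NULL,
                                closing_kernel_px = 5, opening_kernel_px = 5) {
  if (hue_threshold < 0 || hue_threshold > 179)
    stop_validation("hue_threshold must lie in [0, 179]")
  if (area_bounds[1] >= area_bounds[2] || bbox_bounds[1] >= bbox_bounds[2])
    stop_validation("bounds must be ordered (lo, hi)")
  if (shape_score_max <= 0) stop_validation("shape_score_max must be > 0")
  for (k in c(closing_kernel_px, opening_kernel_px))
    if (!is_count(k) || k <= 0 || k %% 2 == 0)
      stop_validation("morphology kernels must be odd positive integers")
  structure(list(hue_threshold = hue_threshold, area_bounds = area_bounds,
                 bbox_bounds = bbox_bounds, shape_score_max = shape_score_max,
                 template = template, closing_kernel_px = closing_kernel_px,
                 opening_kernel_px = opening_kernel_px),
            class = "segmentation_params")
}

#' Extract the hue channel of a scene
#'
#' Converts the RGB render to HSV and returns hue on the 0-179 scale
#' (pure red = 0).
#'
#' @param scene a [depth_scene()] with a color render.
#' @return H x W numeric hue matrix.
#' @export
hue_channel <- function(scene) {
  if (is.null(scene$color))
    stop_validation("scene has no color render; hue extraction needs one")
  d <- dim(scene$color)
  rgb <- rbind(as.numeric(scene$color[, , 1]),
               as.numeric(scene$color[, , 2]),
               as.numeric(scene$color[, , 3]))
  h <- grDevices::rgb2hsv(rgb, maxColorValue = 255)[1, ]
  matrix(h * 180, d[1], d[2])
}

#' Binarize a hue matrix at a threshold
#'
#' Pixels strictly above the threshold become foreground (1); pixels at or
#' below it become background (0).
#'
#' @param hue numeric matrix.
#' @param threshold hue cut.
#' @return integer {0,1} matrix.
#' @export
binarize <- function(hue, threshold = 60) {
  (hue > threshold) + 0L
}

#' Morphological cleanup of a binary mask
#'
#' Closing (with hole filling) to make detected objects solid, then opening
#' to remove small noise and split barely-touching objects.
#'
#' @param mask integer {0,1} matrix.
#' @param params [segmentation_params()] (kernel sizes).
#' @return cleaned integer {0,1} matrix.
#' @export
clean_mask <- function(mask, params = segmentation_params()) {
  m <- (mask != 0) + 0
  m <- EBImage::closing(m, EBImage::makeBrush(params$closing_kernel_px, "disc"))
  m <- EBImage::fillHull(m)
  m <- EBImage::opening(m, EBImage::makeBrush(params$opening_kernel_px, "disc"))
  storage.mode(m) <- "integer"
  matrix(m, nrow(mask), ncol(mask))
}

#' Extract candidate contours from a binary mask
#'
#' Connected foreground components, each returned as a [as_calf_contour()]
#' with its filled area and bounding-box sides.
#'
#' @param mask integer {0,1} matrix.
#' @param min_area_px components smaller than this are not traced (speed
#'   guard; well below any acceptance bound).
#' @return list of `calf_contour` objects, largest area first.
#' @export
extract_contours <- function(mask, min_area_px = 64) {
  lab <- EBImage::bwlabel((mask != 0) + 0)
  n <- max(lab)
  if (n == 0) return(list())
  out <- list()
  tabs <- tabulate(lab[lab > 0], nbins = n)
  for (i in seq_len(n)) {
    if (tabs[i] < min_area_px) next
    idx <- which(lab == i, arr.ind = TRUE)
    rr <- range(idx[, 1]); cc <- range(idx[, 2])
    sub <- (lab[rr[1]:rr[2], cc[1]:cc[2], drop = FALSE] == i) + 0L
    out[[length(out) + 1]] <- as_calf_contour(sub, offset = c(rr[1] - 1L, cc[1] - 1L))
  }
  out[order(vapply(out, function(ct) -ct$area_px, numeric(1)))]
}

segmentation_result <- function(status, contour = NULL, mask = NULL,
                                diagnostics = NULL) {
  structure(list(status = status, contour = contour, mask = mask,
                 diagnostics = diagnostics),
            class = "segmentation_result")
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat(sprintf("segmentation_result: %s", x$status))
  if (x$status == "success")
    cat(sprintf(" (area %d px, bbox %d x %d)", as.integer(x$contour$area_px),
                as.integer(x$contour$bbox_w), as.integer(x$contour$bbox_l)))
  cat("\n")
  invisible(x)
}

#' Select the target calf contour among candidates
#'
#' Filters are applied in order: (1) template shape score <=
#' `shape_score_max`; (2) filled area within `area_bounds`; (3) both
#' bounding-box sides within `bbox_bounds`. Among survivors the
#' largest-area contour wins. The status records the first filter that
#' eliminated every remaining candidate: `no_contours`, `no_match`,
#' `failed_area`, `failed_bbox`, or `success`.
#'
#' @param contours list of `calf_contour` candidates.
#' @param params [segmentation_params()]; its `template` must be set.
#' @return a `segmentation_result`; `$diagnostics` holds one row per
#'   candidate with its score and measurements.
#' @export
select_target <- function(contours, params = segmentation_params()) {
  template <- params$template
  if (is.null(template)) template <- make_template_contour()
  if (length(contours) == 0)
    return(segmentation_result("no_contours",
                               diagnostics = empty_diagnostics()))
  diag <- data.frame(
    candidate = seq_along(contours),
    shape_score = vapply(contours, shape_score, numeric(1), template = template),
    area_px = vapply(contours, function(ct) ct$area_px, numeric(1)),
    bbox_w = vapply(contours, function(ct) ct$bbox_w, numeric(1)),
    bbox_l = vapply(contours, function(ct) ct$bbox_l, numeric(1)))
  pass_shape <- diag$shape_score <= params$shape_score_max
  if (!any(pass_shape))
    return(segmentation_result("no_match", diagnostics = diag))
  pass_area <- pass_shape & diag$area_px >= params$area_bounds[1] &
    diag$area_px <= params$area_bounds[2]
  if (!any(pass_area))
    return(segmentation_result("failed_area", diagnostics = diag))
  pass_bbox <- pass_area &
    diag$bbox_w >= params$bbox_bounds[1] & diag$bbox_w <= params$bbox_bounds[2] &
    diag$bbox_l >= params$bbox_bounds[1] & diag$bbox_l <= params$bbox_bounds[2]
  if (!any(pass_bbox))
    return(segmentation_result("failed_bbox", diagnostics = diag))
  win <- which(pass_bbox)[which.max(diag$area_px[pass_bbox])]
  diag$selected <- seq_len(nrow(diag)) == win
  segmentation_result("success", contour = contours[[win]], diagnostics = diag)
}

empty_diagnostics <- function() {
  data.frame(candidate = integer(), shape_score = numeric(),
             area_px = numeric(), bbox_w = numeric(), bbox_l = numeric())
}

#' Segment a depth scene
#'
#' Full rule-based pipeline: hue extraction, binary thresholding,
#' morphological cleanup, contour extraction, candidate selection. On
#' success the result carries the filled mask of the selected contour at
#' full scene size. Deterministic (no randomness anywhere in the pipeline).
#'
#' @param scene a [depth_scene()] with a color render.
#' @param params [segmentation_params()].
#' @return a `segmentation_result`.
#' @export
segment_scene <- function(scene, params = segmentation_params()) {
  if (is.null(params$template))
    params$template <- make_template_contour(
      scene_config(image_size = dim(scene$depth),
                   camera_height_mm = scene$camera_height_mm))
  hue <- hue_channel(scene)
  bin <- binarize(hue, params$hue_threshold)
  cleaned <- clean_mask(bin, params)
  res <- select_target(extract_contours(cleaned), params)
  if (res$status == "success") {
    full <- matrix(0L, nrow(cleaned), ncol(cleaned))
    ct <- res$contour
    off <- ct$offset
    full[(off[1] + 1):(off[1] + nrow(ct$mask)),
         (off[2] + 1):(off[2] + ncol(ct$mask))] <- ct$mask
    res$mask <- full
  }
  res
}

#' Segment a batch of scenes into a results table
#'
#' @param scenes list of [depth_scene()] objects (or of `list(scene, mask)`
#'   pairs as returned by [render_scene()], in which case ground-truth IoU
#'   is reported too).
#' @param params [segmentation_params()].
#' @return data.frame with one row per frame: frame_id, status, area,
#'   bbox_w, bbox_l, shape_score (winning candidate where successful), and
#'   iou when ground truth was supplied.
#' @export
segment_batch <- function(scenes, params = segmentation_params()) {
  rows <- lapply(scenes, function(s) {
    truth <- NULL
    if (!inherits(s, "depth_scene") && is.list(s) && !is.null(s$scene)) {
      truth <- s$mask; s <- s$scene
    }
    res <- segment_scene(s, params)
    ok <- res$status == "success"
    data.frame(frame_id = s$frame_id, status = res$status,
               area_px = if (ok) res$contour$area_px else NA_real_,
               bbox_w = if (ok) res$contour$bbox_w else NA_real_,
               bbox_l = if (ok) res$contour$bbox_l else NA_real_,
               shape_score = if (ok)
                 res$diagnostics$shape_score[res$diagnostics$selected]
                 else NA_real_,
               iou = if (ok && !is.null(truth)) mask_iou(res$mask, truth)
                     else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
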