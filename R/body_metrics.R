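# Body metrics from a segmented contour plus its depth map: width, length
# (bounding-box sides, width = shorter side), filled contour area (px),
# average height (mm) and volume (mm * px^2, the per-pixel height sum).
# Missing depth readings inside the contour are imputed with the mean
# height of the valid in-contour pixels.

#' Per-pixel calf height above the floor inside a mask
#'
#' Height is `camera_height_mm - depth`, clipped at 0 (sensor readings
#' below the floor plane are noise). Missing readings (depth 0) inside the
#' mask are imputed with the mean height of the valid in-mask pixels;
#' pixels outside the mask are returned as NA.
#'
#' @param scene a [depth_scene()].
#' @param mask integer {0,1} matrix, same shape as the scene.
#' @return numeric matrix of heights (mm), NA outside the mask.
#' @export
height_map <- function(scene, mask) {
  if (!all(dim(mask) == dim(scene$depth)))
    stop_validation("mask and scene shapes differ")
  inmask <- mask != 0
  valid <- inmask & scene$depth > 0
  if (!any(valid))
    stop_validation("all in-mask depth readings are missing; frame unusable")
  h <- matrix(NA_real_, nrow(mask), ncol(mask))
  h[valid] <- pmax(scene$camera_height_mm - scene$depth[valid], 0)
  h[inmask & !valid] <- mean(h[valid])
  h
}

#' Compute body metrics for a successfully segmented frame
#'
#' @param scene a [depth_scene()].
#' @param result a `segmentation_result` with status `"success"` (or a
#'   plain {0,1} mask).
#' @return one-row data.frame: frame_id, calf_id, date, width_px,
#'   length_px, contour_area_px2, avg_height_mm, volume_mm_px2. By
#'   construction `volume = avg_height * area`.
#' @export
compute_metrics <- function(scene, result) {
  if (inherits(result, "segmentation_result")) {
    if (result$status != "success")
      stop_validation("compute_metrics needs a successful segmentation (got '%s')",
                      result$status)
    mask <- result$mask
  } else mask <- (result != 0) + 0L
  h <- height_map(scene, mask)
  idx <- which(mask != 0, arr.ind = TRUE)
  sides <- sort(c(diff(range(idx[, 1])) + 1, diff(range(idx[, 2])) + 1))
  area <- nrow(idx)
  vol <- sum(h[mask != 0])
  data.frame(frame_id = scene$frame_id,
             calf_id = scene$calf_id, date = scene$capture_date,
             width_px = sides[1], length_px = sides[2],
             contour_area_px2 = area,
             avg_height_mm = vol / area,
             volume_mm_px2 = vol,
             stringsAsFactors = FALSE)
}

#' Median body metrics per calf and date
#'
#' Each calf has several frames per visit; the per-(calf, date) median of
#' every metric is the value carried into correlation and prediction
#' analyses. Even group sizes use the mean of the two middle values.
#'
#' @param records data.frame of per-frame metrics (rows from
#'   [compute_metrics()]), with calf_id and date set.
#' @return data.frame keyed by (calf_id, date) with median metrics and
#'   `n_frames`.
#' @export
aggregate_median <- function(records) {
  if (anyNA(records$calf_id) || anyNA(records$date))
    stop_validation("every record needs calf_id and date for aggregation")
  cols <- intersect(c("width_px", "length_px", "contour_area_px2",
                      "avg_height_mm", "volume_mm_px2"), names(records))
  key <- interaction(records$calf_id, records$date, drop = TRUE)
  out <- do.call(rbind, lapply(split(records, key), function(g) {
    row <- data.frame(calf_id = g$calf_id[1], date = g$date[1],
                      n_frames = nrow(g), stringsAsFactors = FALSE)
    for (cl in cols) row[[cl]] <- median(g[[cl]])
    row
  }))
  rownames(out) <- NULL
  out[order(out$calf_id, out$date), , drop = FALSE]
}
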