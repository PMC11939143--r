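# I/O and core containers: depth scenes, masks, polygon annotations,
# longitudinal observation tables.
#
# Conventions (fixed across the package):
#   * pixel coordinates are (row, col), 0-based, row 0 at the top;
#   * masks are integer {0,1} matrices, H x W;
#   * depth is in millimetres, 0 marks a missing reading ("black pixel");
#   * depth CSV files are one image row per line, comma-separated, no header.

#' Construct a depth scene
#'
#' A depth scene pairs a per-pixel camera-to-surface distance matrix (the
#' depth map, in mm) with its colorized render, plus provenance. The camera
#' looks straight down from `camera_height_mm` above the floor (1510 mm in
#' the recording setup this package emulates), so calf height above the floor
#' is `camera_height_mm - depth`.
#'
#' @param depth numeric H x W matrix of distances in mm; 0 = missing reading.
#' @param color H x W x 3 array of RGB values in 0..255, or NULL for a
#'   depth-only scene.
#' @param frame_id character scalar identifying the frame.
#' @param calf_id,capture_date optional provenance.
#' @param camera_height_mm camera mounting height above the floor, mm.
#' @return an object of class `depth_scene`.
#' @export
depth_scene <- function(depth, color = NULL, frame_id = "frame",
                        calf_id = NA_character_, capture_date = NA_character_,
                        camera_height_mm = 1510) {
  if (!is.matrix(depth) || !is.numeric(depth))
    stop_validation("depth must be a numeric matrix")
  if (any(depth < 0, na.rm = TRUE))
    stop_validation("depth values must be >= 0 (0 encodes missing)")
  if (!is.numeric(camera_height_mm) || camera_height_mm <= 0)
    stop_validation("camera_height_mm must be positive")
  if (!is.null(color)) {
    if (length(dim(color)) != 3 || dim(color)[3] != 3)
      stop_validation("color must be an H x W x 3 array")
    if (!all(dim(color)[1:2] == dim(depth)))
      stop_validation("color and depth must share the same H x W")
  }
  structure(list(depth = depth, color = color, frame_id = as.character(frame_id),
                 calf_id = calf_id, capture_date = capture_date,
                 camera_height_mm = camera_height_mm),
            class = "depth_scene")
}

#' @export
print.depth_scene <- function(x, ...) {
  d <- dim(x$depth)
  cat(sprintf("depth_scene '%s': %d x %d px, camera %.0f mm, %s color, %.1f%% missing depth\n",
              x$frame_id, d[1], d[2], x$camera_height_mm,
              if (is.null(x$color)) "no" else "with",
              100 * mean(x$depth == 0)))
  invisible(x)
}

#' Read a depth map from CSV
#'
#' One image row per line, comma-separated, no header. Cells equal to
#' `missing_sentinel` are mapped to 0 (the package's missing-depth code).
#'
#' @param path CSV file path.
#' @param missing_sentinel value encoding a missing reading in the file.
#' @return numeric H x W matrix of depths in mm.
#' @export
read_depth_csv <- function(path, missing_sentinel = 0) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) stop_validation("empty depth CSV: %s", path)
  fields <- strsplit(lines, ",", fixed = TRUE)
  n <- lengths(fields)
  if (length(unique(n)) != 1)
    stop_validation("ragged depth CSV (row lengths %s): %s",
                    paste(unique(n), collapse = "/"), path)
  vals <- suppressWarnings(as.numeric(unlist(fields)))
  if (anyNA(vals))
    stop_validation("non-numeric cell in depth CSV: %s", path)
  m <- matrix(vals, nrow = length(lines), ncol = n[1], byrow = TRUE)
  m[m == missing_sentinel] <- 0
  m
}

#' Write a depth map to CSV
#'
#' Inverse of [read_depth_csv()]: one image row per line, no header.
#'
#' @param depth numeric matrix of depths in mm.
#' @param path output file path.
#' @export
write_depth_csv <- function(depth, path) {
  if (!is.matrix(depth)) stop_validation("depth must be a matrix")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(apply(depth, 1, paste, collapse = ","), con)
  invisible(path)
}

#' Create a polygon annotation
#'
#' Vertices are (row, col) pairs, 0-based, outlining the target contour.
#'
#' @param frame_id frame the annotation refers to.
#' @param vertices n x 2 numeric matrix of (row, col), n >= 3.
#' @return an object of class `polygon_annotation`.
#' @export
polygon_annotation <- function(frame_id, vertices) {
  vertices <- as.matrix(vertices)
  if (nrow(vertices) < 3 || ncol(vertices) != 2 || anyNA(vertices))
    stop_validation("polygon needs >= 3 finite (row, col) vertices")
  structure(list(frame_id = as.character(frame_id), vertices = vertices),
            class = "polygon_annotation")
}

#' Read polygon annotations from JSON
#'
#' Format: a JSON array of objects `{"frame_id": ..., "vertices": [[r, c], ...]}`
#' with 0-based (row, col) vertices.
#'
#' @param path JSON file path.
#' @return list of [polygon_annotation()] objects.
#' @export
read_polygons_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  lapply(raw, function(p) {
    v <- p$vertices
    if (is.list(v)) v <- do.call(rbind, v)
    polygon_annotation(p$frame_id, v)
  })
}

#' Write polygon annotations to JSON
#' @param annotations list of [polygon_annotation()] objects.
#' @param path output file path.
#' @export
write_polygons_json <- function(annotations, path) {
  jsonlite::write_json(
    lapply(annotations, function(a)
      list(frame_id = a$frame_id,
           vertices = lapply(seq_len(nrow(a$vertices)),
                             function(i) unname(a$vertices[i, ])))),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# 0-based integer pixels on the segment (r0,c0)-(r1,c1), Bresenham-style.
# Used to make polygon boundaries inclusive: mgcv::in.out tests strict
# interior only.
line_pixels <- function(r0, c0, r1, c1) {
  n <- max(abs(r1 - r0), abs(c1 - c0)) + 1
  cbind(round(seq(r0, r1, length.out = n)), round(seq(c0, c1, length.out = n)))
}

#' Rasterize polygon annotations to a binary mask
#'
#' Fills each polygon (interior plus boundary pixels) and takes the union
#' over annotations, producing the solid ground-truth mask used for
#' segmentation scoring.
#'
#' @param annotations list of [polygon_annotation()] objects (possibly empty).
#' @param shape integer (H, W) of the target mask.
#' @return integer H x W matrix in {0, 1}.
#' @export
polygons_to_mask <- function(annotations, shape) {
  H <- shape[1]; W <- shape[2]
  mask <- matrix(0L, H, W)
  for (a in annotations) {
    if (!inherits(a, "polygon_annotation")) a <- polygon_annotation("", a)
    v <- a$vertices
    if (any(v[, 1] < 0 | v[, 1] > H - 1 | v[, 2] < 0 | v[, 2] > W - 1))
      stop_validation("polygon vertices outside image bounds")
    rlim <- floor(min(v[, 1])):ceiling(max(v[, 1]))
    clim <- floor(min(v[, 2])):ceiling(max(v[, 2]))
    grid <- cbind(rep(rlim, times = length(clim)),
                  rep(clim, each = length(rlim)))
    inside <- mgcv::in.out(rbind(v, v[1, , drop = FALSE]),
                           matrix(as.numeric(grid), ncol = 2))
    px <- grid[inside, , drop = FALSE]
    # boundary pixels (in.out is boundary-exclusive)
    vv <- rbind(v, v[1, , drop = FALSE])
    for (i in seq_len(nrow(vv) - 1))
      px <- rbind(px, line_pixels(vv[i, 1], vv[i, 2], vv[i + 1, 1], vv[i + 1, 2]))
    px <- px[px[, 1] >= 0 & px[, 1] <= H - 1 & px[, 2] >= 0 & px[, 2] <= W - 1, ,
             drop = FALSE]
    mask[cbind(px[, 1] + 1L, px[, 2] + 1L)] <- 1L
  }
  mask
}

#' Write a depth scene as a PNG + CSV pair
#'
#' `<frame_id>_color.png` (8-bit RGB) and `<frame_id>_depth.csv` in `dir`.
#'
#' @param scene a [depth_scene()] with a color render.
#' @param dir output directory (created if needed).
#' @return the frame's file prefix, invisibly.
#' @export
write_scene <- function(scene, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  prefix <- file.path(dir, scene$frame_id)
  write_depth_csv(scene$depth, paste0(prefix, "_depth.csv"))
  # EBImage stores images as (x = col, y = row)
  img <- aperm(scene$color, c(2, 1, 3)) / 255
  EBImage::writeImage(EBImage::Image(img, colormode = "Color"),
                      paste0(prefix, "_color.png"))
  invisible(prefix)
}

#' Read a depth scene from a PNG + CSV pair
#'
#' @param prefix path prefix, i.e. `dir/frame_id` with `_color.png` and
#'   `_depth.csv` appended.
#' @param camera_height_mm camera height carried onto the scene.
#' @return a [depth_scene()].
#' @export
read_scene <- function(prefix, camera_height_mm = 1510) {
  depth <- read_depth_csv(paste0(prefix, "_depth.csv"))
  img <- EBImage::readImage(paste0(prefix, "_color.png"))
  color <- round(aperm(img, c(2, 1, 3)) * 255)
  depth_scene(depth, color, frame_id = basename(prefix),
              camera_height_mm = camera_height_mm)
}

#' Read a longitudinal calf observation table
#'
#' Required columns: `calf_id`, `date`, `age_days`, `bw_lb`. Body-metric
#' columns (`width_px`, `length_px`, `contour_area_px2`, `avg_height_mm`,
#' `volume_mm_px2`) are carried through when present. Rows are validated and
#' sorted by (calf_id, age_days).
#'
#' @param path CSV file path.
#' @return a validated data.frame sorted by calf and age.
#' @export
read_observations <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_observations(tab)
}

#' Validate (and sort) a calf observation table
#'
#' @param tab data.frame with at least calf_id, date, age_days, bw_lb.
#' @return the table, sorted by (calf_id, age_days).
#' @export
validate_observations <- function(tab) {
  need <- c("calf_id", "date", "age_days", "bw_lb")
  missing <- setdiff(need, names(tab))
  if (length(missing))
    stop_validation("observation table lacks column(s): %s",
                    paste(missing, collapse = ", "))
  if (anyNA(tab$age_days) || any(tab$age_days < 0))
    stop_validation("age_days must be non-negative and non-missing")
  if (anyNA(tab$bw_lb) || any(tab$bw_lb < 0))
    stop_validation("bw_lb must be non-negative and non-missing")
  key <- paste(tab$calf_id, tab$date, sep = "\r")
  if (anyDuplicated(key))
    stop_validation("duplicate (calf_id, date) rows: %s",
                    paste(unique(sub("\r", "/", key[duplicated(key)])), collapse = ", "))
  tab$calf_id <- as.character(tab$calf_id)
  tab[order(tab$calf_id, tab$age_days), , drop = FALSE]
}

#' Write a calf observation table to CSV
#' @param tab observation table.
#' @param path output file path.
#' @export
write_observations <- function(tab, path) {
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}
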