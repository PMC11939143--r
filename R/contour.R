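# Contour objects and moment-invariant shape matching.
#
# A calf_contour carries the closed outline (0-based (row, col) vertices),
# the filled pixel region it bounds (as a local-window mask plus offset), and
# its measurements: filled area in px and axis-aligned bounding-box sides.
# The bounding-box sides are reported canonically as width = shorter side,
# length = longer side.

new_calf_contour <- function(vertices, mask, offset, area_px, bbox_w, bbox_l) {
  structure(list(vertices = vertices, mask = mask, offset = offset,
                 area_px = area_px, bbox_w = bbox_w, bbox_l = bbox_l),
            class = "calf_contour")
}

#' Build a contour object from a binary mask region
#'
#' Traces the outer boundary of the (single) foreground region and records
#' its filled pixel count and bounding-box sides.
#'
#' @param mask integer {0,1} matrix containing one connected foreground
#'   region.
#' @param offset 0-based (row, col) of `mask[1,1]` within the full image
#'   (default c(0, 0)).
#' @return a `calf_contour`.
#' @export
as_calf_contour <- function(mask, offset = c(0, 0)) {
  mask <- (mask != 0) + 0L
  if (sum(mask) == 0) stop_validation("cannot build a contour from an empty mask")
  oc <- EBImage::ocontour(mask)[[1]]
  idx <- which(mask == 1L, arr.ind = TRUE)
  rr <- range(idx[, 1]); cc <- range(idx[, 2])
  sides <- sort(c(diff(rr) + 1L, diff(cc) + 1L))
  new_calf_contour(vertices = sweep(oc, 2, offset, "+"),
                   mask = mask, offset = offset,
                   area_px = sum(mask), bbox_w = sides[1], bbox_l = sides[2])
}

#' @export
print.calf_contour <- function(x, ...) {
  cat(sprintf("calf_contour: area %d px, bbox %d x %d px, %d boundary points\n",
              as.integer(x$area_px), as.integer(x$bbox_w),
              as.integer(x$bbox_l), nrow(x$vertices)))
  invisible(x)
}

# Region Hu moment invariants of a filled binary region. Returns the 7
# classical invariants computed from normalized central moments, which are
# translation, scale and rotation invariant.
hu_moments <- function(mask) {
  idx <- which(mask != 0, arr.ind = TRUE)
  if (nrow(idx) == 0) return(rep(0, 7))
  x <- idx[, 2]; y <- idx[, 1]
  m00 <- length(x)
  xb <- mean(x); yb <- mean(y)
  dx <- x - xb; dy <- y - yb
  mu <- function(p, q) sum(dx^p * dy^q)
  eta <- function(p, q) mu(p, q) / m00^(1 + (p + q) / 2)
  n20 <- eta(2, 0); n02 <- eta(0, 2); n11 <- eta(1, 1)
  n30 <- eta(3, 0); n03 <- eta(0, 3); n21 <- eta(2, 1); n12 <- eta(1, 2)
  h1 <- n20 + n02
  h2 <- (n20 - n02)^2 + 4 * n11^2
  h3 <- (n30 - 3 * n12)^2 + (3 * n21 - n03)^2
  h4 <- (n30 + n12)^2 + (n21 + n03)^2
  h5 <- (n30 - 3 * n12) * (n30 + n12) * ((n30 + n12)^2 - 3 * (n21 + n03)^2) +
    (3 * n21 - n03) * (n21 + n03) * (3 * (n30 + n12)^2 - (n21 + n03)^2)
  h6 <- (n20 - n02) * ((n30 + n12)^2 - (n21 + n03)^2) +
    4 * n11 * (n30 + n12) * (n21 + n03)
  h7 <- (3 * n21 - n03) * (n30 + n12) * ((n30 + n12)^2 - 3 * (n21 + n03)^2) -
    (n30 - 3 * n12) * (n21 + n03) * (3 * (n30 + n12)^2 - (n21 + n03)^2)
  c(h1, h2, h3, h4, h5, h6, h7)
}

#' Moment-invariant shape dissimilarity between two contours
#'
#' The I1 match score over log-scaled Hu moment invariants:
#' \deqn{D(A, B) = \sum_i |1/m_i^A - 1/m_i^B|,\quad m_i = sign(h_i) \log_{10} |h_i|,}
#' computed from the filled regions. 0 means identical shapes; the score is
#' invariant to translation, scale and rotation; smaller is more similar.
#' Degenerate (zero-area) contours score `Inf`.
#'
#' @param contour,template `calf_contour` objects (or {0,1} mask matrices).
#' @return non-negative dissimilarity, 0 for identical shapes.
#' @export
shape_score <- function(contour, template) {
  region <- function(x) {
    if (inherits(x, "calf_contour")) x$mask
    else if (is.matrix(x)) (x != 0) + 0L
    else stop_validation("shape_score expects calf_contour or mask inputs")
  }
  a <- region(contour); b <- region(template)
  if (sum(a) == 0 || sum(b) == 0) return(Inf)
  ha <- hu_moments(a); hb <- hu_moments(b)
  eps <- 1e-5
  keep <- abs(ha) > eps & abs(hb) > eps
  # the higher-order invariants vanish for symmetric shapes; if nothing is
  # comparable the shapes carry no usable signature -> reject
  if (!any(keep)) return(Inf)
  ma <- sign(ha[keep]) * log10(abs(ha[keep]))
  mb <- sign(hb[keep]) * log10(abs(hb[keep]))
  sum(abs(1 / ma - 1 / mb))
}
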