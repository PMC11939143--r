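# Independent oracles, kept deliberately naive and separate from the
# package's implementation paths.

# Brute-force rasterization: even-odd crossing test per pixel centre, with
# points on an edge counted inside.
oracle_polygon_mask <- function(vertices, shape) {
  H <- shape[1]; W <- shape[2]
  v <- rbind(vertices, vertices[1, , drop = FALSE])
  on_segment <- function(r, c, r0, c0, r1, c1) {
    cross <- (c1 - c0) * (r - r0) - (r1 - r0) * (c - c0)
    if (abs(cross) > 1e-9) return(FALSE)
    r >= min(r0, r1) - 1e-9 && r <= max(r0, r1) + 1e-9 &&
      c >= min(c0, c1) - 1e-9 && c <= max(c0, c1) + 1e-9
  }
  mask <- matrix(0L, H, W)
  for (r in 0:(H - 1)) for (c in 0:(W - 1)) {
    crossings <- 0
    boundary <- FALSE
    for (i in seq_len(nrow(v) - 1)) {
      r0 <- v[i, 1]; c0 <- v[i, 2]; r1 <- v[i + 1, 1]; c1 <- v[i + 1, 2]
      if (on_segment(r, c, r0, c0, r1, c1)) { boundary <- TRUE; break }
      # horizontal ray in +c direction, crossing edges in r
      if ((r0 > r) != (r1 > r)) {
        c_at <- c0 + (r - r0) / (r1 - r0) * (c1 - c0)
        if (c_at > c) crossings <- crossings + 1
      }
    }
    if (boundary || crossings %% 2 == 1) mask[r + 1, c + 1] <- 1L
  }
  mask
}

# Long-form one-way ANOVA from explicit sums of squares.
oracle_anova <- function(values, groups) {
  groups <- as.factor(groups)
  grand <- mean(values)
  ss_total <- sum((values - grand)^2)
  ss_between <- sum(tapply(values, groups, function(g)
    length(g) * (mean(g) - grand)^2))
  ss_within <- ss_total - ss_between
  df_b <- nlevels(groups) - 1
  df_w <- length(values) - nlevels(groups)
  f <- (ss_between / df_b) / (ss_within / df_w)
  list(f = f, p = stats::pf(f, df_b, df_w, lower.tail = FALSE),
       eta_sq = ss_between / ss_total)
}

# Naive binary erosion/dilation with a square 3x3 structuring element.
oracle_erode3 <- function(m) {
  H <- nrow(m); W <- ncol(m)
  out <- matrix(0L, H, W)
  for (r in 2:(H - 1)) for (c in 2:(W - 1))
    if (all(m[(r - 1):(r + 1), (c - 1):(c + 1)] == 1)) out[r, c] <- 1L
  out
}
oracle_dilate3 <- function(m) {
  H <- nrow(m); W <- ncol(m)
  out <- matrix(0L, H, W)
  for (r in 1:H) for (c in 1:W)
    if (m[r, c] == 1)
      out[max(1, r - 1):min(H, r + 1), max(1, c - 1):min(W, c + 1)] <- 1L
  out
}
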