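# Programmatic fixtures and independent oracles used across the suite.

# Solid-color image of the given size.
flat_image <- function(rows, cols, rgb) {
  img <- array(0L, dim = c(rows, cols, 3L))
  for (k in 1:3) img[, , k] <- as.integer(rgb[k])
  img
}

# Gray image from a matrix by replicating the value across channels.
gray_as_color <- function(m) {
  img <- array(0L, dim = c(nrow(m), ncol(m), 3L))
  for (k in 1:3) img[, , k] <- as.integer(m)
  img
}

# Brute-force polygon area by fan triangulation from the first vertex
# (valid for convex polygons): sum of |cross product| / 2.
triangulation_area <- function(v) {
  n <- nrow(v)
  a <- 0
  for (i in 2:(n - 1)) {
    u <- v[i, ] - v[1, ]
    w <- v[i + 1, ] - v[1, ]
    a <- a + abs(u[1] * w[2] - u[2] * w[1]) / 2
  }
  a
}

# Random convex polygon with up to max_v vertices, as ordered (x, y) rows.
random_convex_polygon <- function(max_v = 12) {
  repeat {
    pts <- matrix(stats::runif(2 * (max_v + 6), -10, 10), ncol = 2)
    hull <- pts[grDevices::chull(pts), , drop = FALSE]
    if (nrow(hull) >= 3 && nrow(hull) <= max_v) return(hull)
  }
}

# Naive double-loop histogram oracle.
naive_histogram <- function(m) {
  h <- numeric(256)
  for (v in as.vector(m)) h[v + 1] <- h[v + 1] + 1
  h
}

# Brute-force 0-based half-open bounding box of foreground pixels.
pixel_bbox <- function(mask) {
  px <- which(mask > 0, arr.ind = TRUE)
  c(x_min = min(px[, 2]) - 1L, x_max = max(px[, 2]),
    y_min = min(px[, 1]) - 1L, y_max = max(px[, 1]))
}

# Gray scene with a rectangular band of the given intensity, rotated by
# `tilt` degrees about the image center (inverse nearest-neighbor map),
# on a uniform background.
rotated_band_scene <- function(rows, cols, band_rows, band_cols, value,
                               tilt = 0, background = 0) {
  cy <- (rows - 1) / 2; cx <- (cols - 1) / 2
  t <- tilt * pi / 180
  m <- matrix(as.integer(background), rows, cols)
  for (r in 0:(rows - 1)) for (cc in 0:(cols - 1)) {
    sx <- round(cos(t) * (cc - cx) + sin(t) * (r - cy) + cx)
    sy <- round(-sin(t) * (cc - cx) + cos(t) * (r - cy) + cy)
    if (sy >= band_rows[1] && sy <= band_rows[2] &&
        sx >= band_cols[1] && sx <= band_cols[2])
      m[r + 1, cc + 1] <- as.integer(value)
  }
  m
}
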