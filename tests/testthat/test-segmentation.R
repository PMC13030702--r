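test_that("grayscale conversion uses BT.601 luma with round-half-up", {
  expect_equal(to_grayscale(flat_image(3, 3, c(255, 255, 255))),
               matrix(255L, 3, 3))
  expect_equal(to_grayscale(flat_image(3, 3, c(0, 0, 0))), matrix(0L, 3, 3))
  # round(0.299 * 255) = 76 for a pure red pixel
  expect_equal(to_grayscale(flat_image(2, 1, c(255, 0, 0)))[1, 1], 76L)
  # hand-computed luma: 0.299*10 + 0.587*20 + 0.114*30 = 18.15 -> 18
  expect_equal(to_grayscale(flat_image(2, 1, c(10, 20, 30)))[1, 1], 18L)
  expect_error(to_grayscale(array(0L, c(0, 0, 3))), "invalid")
})

test_that("binarization is a strict threshold and idempotent", {
  g <- matrix(c(20L, 21L, 0L, 255L), 2, 2)
  m <- binarize(g, 20)
  expect_equal(m, matrix(c(0L, 255L, 0L, 255L), 2, 2))
  expect_equal(binarize(matrix(0L, 4, 4), 20), matrix(0L, 4, 4))
  # idempotence for any threshold: the 0/255 mask rebinarizes to itself
  for (Tb in c(0, 20, 90, 254)) {
    g2 <- matrix(sample(0:255, 64, replace = TRUE), 8, 8)
    m1 <- binarize(g2, Tb)
    expect_identical(binarize(m1, Tb), m1)
  }
})

test_that("shoelace area matches closed forms and a triangulation oracle", {
  expect_equal(polygon_area(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))), 1)
  expect_equal(polygon_area(rbind(c(0, 0), c(4, 0), c(0, 3))), 6)
  expect_equal(polygon_area(rbind(c(0, 0), c(1, 1), c(2, 2))), 0)
  expect_error(polygon_area(rbind(c(0, 0), c(1, 1))), "degenerate")
  # orientation independence
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  expect_equal(polygon_area(sq[4:1, ]), 1)
  set.seed(71)
  for (i in 1:25) {
    poly <- random_convex_polygon(12)
    expect_equal(polygon_area(poly), triangulation_area(poly),
                 tolerance = 1e-9)
  }
})

test_that("capillary ROI selection validates area and matches the pixel bbox oracle", {
  cfg <- seg_config(min_area = 100)
  m <- matrix(0L, 120, 40)
  m[11:101, 21:31] <- 255L       # rows 10-100, cols 20-30 (0-based)
  r <- find_capillary_roi(m, cfg)
  expect_equal(unlist(r[c("x_min", "x_max", "y_min", "y_max")]),
               c(x_min = 20L, x_max = 31L, y_min = 10L, y_max = 101L))
  expect_error(find_capillary_roi(matrix(0L, 10, 10), cfg), "not found")
  # two blobs: the small one is filtered by min_area, the large one wins
  m2 <- matrix(0L, 80, 80)
  m2[5:29, 5:25] <- 255L         # 25 x 21 = 525 px^2
  m2[60:67, 60:66] <- 255L       # 8 x 7 = 56 px^2
  r2 <- find_capillary_roi(m2, cfg)
  expect_equal(c(r2$x_min, r2$x_max, r2$y_min, r2$y_max), c(4L, 25L, 4L, 29L))
})

test_that("selected-contour bounding box equals the pixel min/max oracle on random blobs", {
  set.seed(5)
  for (i in 1:15) {
    m <- matrix(0L, 40, 40)
    r0 <- sample(4:20, 1); c0 <- sample(4:20, 1)
    h <- sample(6:15, 1); w <- sample(6:15, 1)
    m[r0:(r0 + h), c0:(c0 + w)] <- 255L
    # carve random notches so the blob is not a plain rectangle
    for (k in 1:4) m[sample(r0:(r0 + h), 1), sample(c0:(c0 + w), 1)] <- 0L
    m[r0:(r0 + h), c0] <- 255L   # keep the extreme column populated
    bb <- pixel_bbox(m)
    r <- find_capillary_roi(m, seg_config(min_area = 10))
    expect_equal(c(r$x_min, r$x_max, r$y_min, r$y_max), unname(bb))
  }
})

test_that("ROI split uses the floor midpoint", {
  r <- roi(0, 5, 0, 10)
  s <- split_roi(r, orientation = "top")
  expect_equal(c(s$roi1$y_min, s$roi1$y_max), c(0L, 5L))
  expect_equal(c(s$roi2$y_min, s$roi2$y_max), c(5L, 10L))
  s2 <- split_roi(roi(0, 5, 0, 11), orientation = "top")
  expect_equal(s2$roi1$y_max, 5L)
  expect_equal(c(s2$roi2$y_min, s2$roi2$y_max), c(5L, 11L))
  s3 <- split_roi(roi(0, 2, 3, 5), orientation = "top")
  expect_equal(c(s3$roi1$y_min, s3$roi1$y_max), c(3L, 4L))
  expect_error(split_roi(roi(0, 2, 3, 4)), "too small")
  # seal-at-bottom flips which half is ROI1
  sb <- split_roi(r, orientation = "bottom")
  expect_equal(sb$roi1$label, "seal")
  expect_equal(c(sb$roi1$y_min, sb$roi1$y_max), c(5L, 10L))
})

test_that("axial profile averages columns and differentiates rows", {
  g <- matrix(50L, 12, 4)
  p <- axial_profile(g, roi(0, 4, 0, 12))
  expect_equal(p$values, rep(50, 12))
  expect_equal(p$gradient, rep(0, 11))
  expect_equal(length(p$gradient), length(p$values) - 1L)
  g2 <- matrix(30L, 16, 3); g2[9:16, ] <- 120L    # step between rows 7 and 8
  p2 <- axial_profile(g2, roi(0, 3, 0, 16))
  expect_equal(p2$gradient[8], 90)                 # 0-based index 7
  expect_equal(sum(p2$gradient != 0), 1L)
  g3 <- matrix(rep(0:9, 2), 10, 2)
  expect_equal(axial_profile(g3, roi(0, 2, 0, 10))$gradient, rep(1, 9))
  expect_error(axial_profile(g, roi(0, 10, 0, 12)), "bounds")
})

test_that("interface locators find the first strict gradient crossing", {
  cfg <- seg_config(grad_thresh = 90)
  seal_prof <- list(values = c(rep(200, 8), rep(60, 12)))
  seal_prof$gradient <- diff(seal_prof$values)
  expect_equal(locate_seal_end(seal_prof, cfg), 7)           # 200 -> 60 step row
  expect_equal(locate_seal_end(seal_prof, seg_config(grad_thresh = 90, h_seal = 3)), 10)
  flat <- list(values = rep(80, 20), gradient = rep(0, 19))
  expect_error(locate_seal_end(flat, cfg), "interface not found")

  # serum -> cream step placing the first cream row at ROI2-relative row 12
  y_mid <- 10
  vals <- c(rep(60, y_mid + 12), rep(140, 8))
  prof <- list(values = vals, gradient = diff(vals))
  expect_equal(locate_cream_start(prof, y_mid, seg_config(grad_thresh = 70)), y_mid + 12)
  expect_error(locate_cream_start(flat, 10, cfg), "interface not found")
  # a step exactly equal to the threshold is not an interface (strict >)
  vals_eq <- c(rep(60, 15), rep(150, 5))
  prof_eq <- list(values = vals_eq, gradient = diff(vals_eq))
  expect_error(locate_cream_start(prof_eq, 5, cfg), "interface not found")

  # cream end: first crossing past the cream start wins; fallback at ROI edge
  vals_end <- c(rep(60, 10), rep(140, 15), rep(220, 6))
  prof_end <- list(values = vals_end, gradient = diff(vals_end))
  e <- locate_cream_end(prof_end, 10, seg_config(grad_thresh = 70))
  expect_equal(as.integer(e), 24L)                 # last cream row
  expect_false(attr(e, "fallback"))
  vals_nf <- c(rep(60, 10), rep(140, 20))
  prof_nf <- list(values = vals_nf, gradient = diff(vals_nf))
  e2 <- locate_cream_end(prof_nf, 10, seg_config(grad_thresh = 70))
  expect_equal(as.integer(e2), 29L)                # ROI far edge
  expect_true(attr(e2, "fallback"))
})

test_that("phase height measures the band length via the minimum-area rectangle", {
  g <- matrix(0L, 60, 20)
  g[11:50, 7:14] <- 60L                            # 40 rows x 8 cols
  ph <- phase_height(g, roi(0, 20, 0, 60), 25, 90)
  expect_equal(ph$height, 40, tolerance = 0.026)   # within +/- 1 px
  # rotated by 5 degrees: still the band length, not its bounding-box height
  g5 <- rotated_band_scene(80, 60, band_rows = c(20, 59), band_cols = c(26, 33),
                           value = 60, tilt = 5)
  ph5 <- phase_height(g5, roi(0, 60, 0, 80), 25, 90)
  expect_equal(ph5$height, 40, tolerance = 0.05)
  expect_error(phase_height(g, roi(0, 20, 0, 60), 200, 250), "phase not found")
})

test_that("adaptive crop keeps serum and cream rows only", {
  img <- gray_as_color(matrix(100L, 100, 10))
  b <- list(y_seal_end = 10L, y_cream_end = 50L)
  crop <- adaptive_crop(img, b, roi(0, 10, 0, 100), orientation = "top")
  expect_equal(dim(crop), c(39L, 10L, 3L))
  b2 <- list(y_seal_end = 10L, y_cream_end = 12L)
  expect_equal(dim(adaptive_crop(img, b2, roi(0, 10, 0, 100), "top"))[1], 1L)
  b3 <- list(y_seal_end = 10L, y_cream_end = 11L)
  expect_error(adaptive_crop(img, b3, roi(0, 10, 0, 100), "top"), "crop failed")
})

test_that("full segmentation recovers the generator's known geometry", {
  out <- render_capillary(capillary_spec(seed = 3))
  seg <- segment_capillary(out$image)
  expect_equal(seg$boundaries$h_t, 227, tolerance = 1 / 227)
  expect_equal(seg$c, out$truth$c, tolerance = 0.005 / out$truth$c)
  expect_equal(seg$boundaries$h_t, seg$boundaries$h_s + seg$boundaries$h_c)
  # tilted scene within the same tolerance
  out5 <- render_capillary(capillary_spec(tilt = 5, seed = 4))
  seg5 <- segment_capillary(out5$image)
  expect_lt(abs(seg5$c - out5$truth$c), 0.005)
  # deterministic for fixed input and config
  seg_b <- segment_capillary(out$image)
  expect_identical(seg$boundaries, seg_b$boundaries)
  # background-only image
  expect_error(segment_capillary(flat_image(50, 30, c(10, 10, 10))),
               "capillary not found")
})

test_that("segmentation config validates thresholds and reads key-value files", {
  expect_error(seg_config(Tb = 30), "Tb < Tmin_g")
  expect_error(seg_config(min_area = 0), "min_area")
  path <- withr::local_tempfile(fileext = ".cfg")
  writeLines(c("# test config", "Tb = 15", "Tw: 95", "orientation = top"), path)
  cfg <- read_seg_config(path)
  expect_equal(cfg$Tb, 15)
  expect_equal(cfg$Tw, 95)
  expect_equal(cfg$orientation, "top")
  writeLines("bogus = 1", path)
  expect_error(read_seg_config(path), "unknown config key")
})
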