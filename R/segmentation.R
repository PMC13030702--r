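## Segmentation of a single vertically oriented microcapillary into its
## seal / serum / cream phases. All coordinates are 0-based with the origin
## at the top-left pixel and y increasing downward; ROIs are half-open.
## Phase boundaries are reported in *axial* coordinates: row 0 is the
## seal-end extremity of the capillary ROI and rows increase along the tube
## toward the cream, independent of whether the seal sits at the top or the
## bottom of the photograph. `y_base` records the image row of that origin.

#' Segmentation configuration
#'
#' Thresholds and geometry offsets for [segment_capillary()] and the
#' stage-level operations.
#'
#' @param Tb Background binarization threshold; pixels with gray value
#'   strictly above `Tb` are foreground. Default 20.
#' @param Tw Intensity threshold separating the bright phases (seal, cream)
#'   from serum and background. Default 90.
#' @param grad_thresh Axial-gradient exceedance threshold used by the
#'   interface locators. Interfaces are declared where the absolute
#'   first difference of the column-averaged profile strictly exceeds this
#'   value. Default 25: below the worst-case per-row contrast of the
#'   weakest interface under 5 degrees of tilt plus meniscus smoothing,
#'   far above profile noise (see the methods vignette).
#' @param Tmin_g,Tmax_g Inclusive gray range of the serum phase.
#'   Defaults 25 and 90.
#' @param h_seal,dy_seal Additive seal allowance and displacement offset in
#'   pixels applied to the detected seal end. Defaults 0.
#' @param dy_cream,h_cream Displacement offset for the cream start and
#'   allowance for the cream end, in pixels. Defaults 0.
#' @param min_area Minimum accepted contour (shoelace) area in px^2 when
#'   searching for the capillary. Default 500.
#' @param orientation Which image end holds the seal: `"bottom"` (default)
#'   or `"top"`.
#' @return A `seg_config` list.
#' @export
seg_config <- function(Tb = 20, Tw = 90, grad_thresh = 25,
                       Tmin_g = 25, Tmax_g = 90,
                       h_seal = 0, dy_seal = 0, dy_cream = 0, h_cream = 0,
                       min_area = 500, orientation = c("bottom", "top")) {
  orientation <- match.arg(orientation)
  cfg <- list(Tb = Tb, Tw = Tw, grad_thresh = grad_thresh,
              Tmin_g = Tmin_g, Tmax_g = Tmax_g,
              h_seal = h_seal, dy_seal = dy_seal,
              dy_cream = dy_cream, h_cream = h_cream,
              min_area = min_area, orientation = orientation)
  if (!(cfg$Tb >= 0 && cfg$Tb < cfg$Tmin_g && cfg$Tmin_g < cfg$Tmax_g &&
        cfg$Tmax_g <= 255))
    stop("invalid config: need 0 <= Tb < Tmin_g < Tmax_g <= 255")
  if (!(cfg$Tw > 0 && cfg$Tw <= 255)) stop("invalid config: Tw must be in (0, 255]")
  if (!(cfg$grad_thresh > 0)) stop("invalid config: grad_thresh must be positive")
  if (!(cfg$min_area > 0)) stop("invalid config: min_area must be positive")
  class(cfg) <- "seg_config"
  cfg
}

#' Read a segmentation configuration from a flat key-value file
#'
#' One `key = value` (or `key: value`) pair per line; `#` starts a comment.
#' Keys are the arguments of [seg_config()]; unknown keys are an error.
#'
#' @param path Path to the configuration file.
#' @return A `seg_config` list.
#' @export
read_seg_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  args <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "[=:]", fixed = FALSE)[[1]]
    if (length(kv) != 2L) stop("malformed config line: '", ln, "'")
    key <- trimws(kv[1]); val <- trimws(kv[2])
    if (!key %in% names(formals(seg_config)))
      stop("unknown config key: '", key, "'")
    args[[key]] <- if (key == "orientation") val else as.numeric(val)
  }
  do.call(seg_config, args)
}

#' Rectangular region of interest
#'
#' Half-open pixel rectangle `[x_min, x_max) x [y_min, y_max)` in 0-based
#' image coordinates.
#'
#' @param x_min,x_max,y_min,y_max Pixel bounds.
#' @param label One of `"general"`, `"seal"`, `"cream"`, `"serum"`.
#' @return A `roi` list.
#' @export
roi <- function(x_min, x_max, y_min, y_max, label = "general") {
  if (!(x_min < x_max && y_min < y_max))
    stop("invalid roi: need x_min < x_max and y_min < y_max")
  structure(list(x_min = as.integer(x_min), x_max = as.integer(x_max),
                 y_min = as.integer(y_min), y_max = as.integer(y_max),
                 label = label),
            class = "roi")
}

roi_height <- function(r) r$y_max - r$y_min
roi_width <- function(r) r$x_max - r$x_min

## Extract the roi's sub-matrix from a gray image (1-based R indexing inside).
roi_pixels <- function(gray, r) {
  if (r$x_min < 0 || r$y_min < 0 || r$x_max > ncol(gray) || r$y_max > nrow(gray))
    stop("roi exceeds image bounds")
  gray[(r$y_min + 1L):r$y_max, (r$x_min + 1L):r$x_max, drop = FALSE]
}

## Map an axial half-open row interval [ax_lo, ax_hi) inside `r` to an
## image-coordinate roi, honoring the seal orientation.
axial_to_image_roi <- function(r, ax_lo, ax_hi, orientation, label = "general") {
  if (orientation == "top")
    roi(r$x_min, r$x_max, r$y_min + ax_lo, r$y_min + ax_hi, label)
  else
    roi(r$x_min, r$x_max, r$y_max - ax_hi, r$y_max - ax_lo, label)
}

#' Convert an RGB image to 8-bit grayscale
#'
#' ITU-R BT.601 luma weights (0.299, 0.587, 0.114), rounded half-up and
#' clamped to `[0, 255]`.
#'
#' @param img Integer array `H x W x 3` with values in `[0, 255]`.
#' @return Integer matrix `H x W`.
#' @export
to_grayscale <- function(img) {
  img <- validate_color_image(img)
  dm <- dim(img)[1:2]
  lum <- 0.299 * matrix(img[, , 1], dm[1], dm[2]) +
         0.587 * matrix(img[, , 2], dm[1], dm[2]) +
         0.114 * matrix(img[, , 3], dm[1], dm[2])
  gray <- floor(lum + 0.5)            # round half up
  gray[gray < 0] <- 0; gray[gray > 255] <- 255
  storage.mode(gray) <- "integer"
  gray
}

#' Global binarization
#'
#' Foreground where the gray value strictly exceeds the threshold.
#'
#' @param gray Integer matrix of 8-bit gray values.
#' @param Tb Threshold in `[0, 255]`.
#' @return Integer matrix of the same shape containing only 0 and 255.
#' @export
binarize <- function(gray, Tb) {
  gray <- validate_gray_image(gray)
  if (Tb < 0 || Tb > 255) stop("Tb must lie in [0, 255]")
  mask <- matrix(0L, nrow(gray), ncol(gray))
  mask[gray > Tb] <- 255L
  mask
}

#' Shoelace polygon area
#'
#' Absolute value of the signed (shoelace) area of a polygon given by its
#' ordered vertices, with cyclic indexing; orientation-independent.
#'
#' @param vertices Two-column matrix of `(x, y)` vertex coordinates.
#' @return Area in px^2.
#' @export
polygon_area <- function(vertices) {
  vertices <- as.matrix(vertices)
  n <- nrow(vertices)
  if (n < 3L) stop("degenerate polygon: need at least 3 vertices")
  x <- vertices[, 1]; y <- vertices[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  abs(sum(x * yn - xn * y)) / 2
}

## 8-connected component labeling: EBImage's 4-connected flood fill followed
## by a union-find merge of diagonally adjacent labels.
label_components8 <- function(fg) {
  lab <- EBImage::bwlabel(fg)
  lab <- matrix(as.integer(lab), nrow(fg), ncol(fg))
  n <- max(lab)
  if (n < 2L) return(lab)
  nr <- nrow(lab); nc <- ncol(lab)
  if (nr > 1L && nc > 1L) {
    pairs <- rbind(
      cbind(as.vector(lab[-nr, -nc]), as.vector(lab[-1, -1])),   # down-right
      cbind(as.vector(lab[-nr, -1]), as.vector(lab[-1, -nc])))   # down-left
    pairs <- pairs[pairs[, 1] > 0L & pairs[, 2] > 0L &
                   pairs[, 1] != pairs[, 2], , drop = FALSE]
    if (nrow(pairs)) {
      parent <- seq_len(n)
      find_root <- function(i) {
        while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }
        i
      }
      for (k in seq_len(nrow(pairs))) {
        ra <- find_root(pairs[k, 1]); rb <- find_root(pairs[k, 2])
        if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
      }
      root <- vapply(seq_len(n), find_root, integer(1))
      relab <- match(root, sort(unique(root)))
      pos <- lab > 0L
      lab[pos] <- relab[lab[pos]]
    }
  }
  lab
}

## Border-following contour of every labeled component, as 0-based (x, y)
## vertex matrices.
component_contours <- function(lab) {
  oc <- EBImage::ocontour(lab)
  lapply(oc, function(m) cbind(x = m[, 2], y = m[, 1]))  # ocontour: (row, col)
}

#' Locate the capillary in a binary mask
#'
#' Extracts 8-connected foreground components, validates each component's
#' border-following contour by its shoelace area against `min_area`, selects
#' the largest-area contour (ties broken by topmost-then-leftmost bounding
#' box) and returns the component's axis-aligned bounding rectangle.
#'
#' @param mask Binary mask matrix (0 / 255).
#' @param cfg A [seg_config()].
#' @return A [roi()] with label `"general"`.
#' @export
find_capillary_roi <- function(mask, cfg = seg_config()) {
  find_capillary_component(mask, cfg)$roi
}

## As find_capillary_roi, but also returns a mask holding only the selected
## component, so downstream profiles are immune to stray foreground noise.
find_capillary_component <- function(mask, cfg = seg_config()) {
  fg <- mask > 0
  if (!any(fg)) stop("capillary not found: empty mask")
  lab <- label_components8(fg)
  conts <- component_contours(lab)
  areas <- vapply(conts, function(v) {
    if (nrow(v) < 3L) 0 else polygon_area(v)
  }, numeric(1))
  keep <- which(areas >= cfg$min_area)
  if (!length(keep))
    stop("capillary not found: no contour with shoelace area >= min_area (",
         cfg$min_area, " px^2)")
  bbox <- function(k) {
    px <- which(lab == k, arr.ind = TRUE)
    c(x_min = min(px[, 2]) - 1L, x_max = max(px[, 2]),
      y_min = min(px[, 1]) - 1L, y_max = max(px[, 1]))
  }
  labels_kept <- as.integer(names(conts)[keep])
  boxes <- t(vapply(labels_kept, bbox, numeric(4)))
  ord <- order(-areas[keep], boxes[, "y_min"], boxes[, "x_min"])
  b <- boxes[ord[1], ]
  comp <- matrix(0L, nrow(mask), ncol(mask))
  comp[lab == labels_kept[ord[1]]] <- 255L
  list(roi = roi(b["x_min"], b["x_max"], b["y_min"], b["y_max"],
                 label = "general"),
       mask = comp)
}

#' Split the capillary ROI at its vertical midpoint
#'
#' The split row is `y_mid = floor(h / 2)` relative to the ROI. ROI1 is the
#' seal-side half and ROI2 the cream-side half according to `orientation`.
#'
#' @param r The capillary [roi()].
#' @param orientation `"bottom"` (seal at the bottom, default) or `"top"`.
#' @return List with elements `roi1` (seal side) and `roi2` (cream side).
#' @export
split_roi <- function(r, orientation = c("bottom", "top")) {
  orientation <- match.arg(orientation)
  h <- roi_height(r)
  if (h < 2L) stop("roi too small to split: height < 2")
  y_mid <- h %/% 2L
  upper <- roi(r$x_min, r$x_max, r$y_min, r$y_min + y_mid)
  lower <- roi(r$x_min, r$x_max, r$y_min + y_mid, r$y_max)
  if (orientation == "bottom") {
    upper$label <- "cream"; lower$label <- "seal"
    list(roi1 = lower, roi2 = upper)
  } else {
    upper$label <- "seal"; lower$label <- "cream"
    list(roi1 = upper, roi2 = lower)
  }
}

#' Column-averaged axial intensity profile
#'
#' Mean gray value across the ROI's columns at each row, together with its
#' first forward difference (the axial intensity gradient). With
#' `seal_from = "bottom"` the profile is reversed so that index 0 is always
#' the seal-end extremity (axial coordinates). When a binary foreground
#' `mask` is supplied, each row averages only its foreground pixels, which
#' keeps interface gradients undiluted when a tilted capillary's bounding
#' box is wider than the tube; rows without foreground inherit the nearest
#' preceding foreground row's value.
#'
#' @param gray Gray image matrix.
#' @param r A [roi()] inside the image.
#' @param seal_from `"top"` (default; no reversal) or `"bottom"`.
#' @param mask Optional binary mask (same shape as `gray`) restricting each
#'   row's average to foreground pixels.
#' @return List with `values` (length = roi height) and `gradient`
#'   (length = roi height - 1), where `gradient[i] = values[i+1] - values[i]`
#'   in 0-based indexing.
#' @export
axial_profile <- function(gray, r, seal_from = c("top", "bottom"),
                          mask = NULL) {
  seal_from <- match.arg(seal_from)
  sub <- roi_pixels(gray, r)
  if (is.null(mask)) {
    vals <- rowMeans(sub)
  } else {
    fg <- roi_pixels(mask, r) > 0
    num <- rowSums(sub * fg)
    den <- rowSums(fg)
    vals <- ifelse(den > 0, num / pmax(den, 1L), NA_real_)
    if (anyNA(vals)) {      # carry the nearest previous foreground value
      for (i in seq_along(vals))
        if (is.na(vals[i])) vals[i] <- if (i > 1) vals[i - 1] else vals[which(!is.na(vals))[1]]
    }
  }
  if (seal_from == "bottom") vals <- rev(vals)
  list(values = vals, gradient = diff(vals))
}

## Shared first-crossing scan: 0-based gradient indices [from, to),
## strict exceedance; returns the first index or NA.
first_crossing <- function(gradient, thresh, from, to) {
  idx <- seq.int(from + 1L, to)              # 1-based R indices
  idx <- idx[idx >= 1L & idx <= length(gradient)]
  hit <- idx[abs(gradient[idx]) > thresh]
  if (!length(hit)) return(NA_integer_)
  hit[1] - 1L                                # back to 0-based
}

#' Locate the lower boundary of the seal
#'
#' Scans the axial gradient from the capillary origin toward the midpoint
#' and returns the first row whose absolute gradient strictly exceeds the
#' threshold, plus the configured displacement `dy_seal` and seal allowance
#' `h_seal`. The returned row is the last seal row in axial coordinates.
#'
#' @param profile An [axial_profile()] of the capillary ROI (or of ROI1).
#' @param cfg A [seg_config()]; `grad_thresh`, `dy_seal` and `h_seal` are used.
#' @param y_mid Optional exclusive axial scan limit (the ROI midpoint).
#' @return Axial row index of the seal end (0-based).
#' @export
locate_seal_end <- function(profile, cfg = seg_config(), y_mid = NULL) {
  to <- if (is.null(y_mid)) length(profile$gradient) else min(y_mid - 1L, length(profile$gradient))
  k <- first_crossing(profile$gradient, cfg$grad_thresh, 0L, to)
  if (is.na(k)) stop("interface not found: no gradient exceedance in the seal region")
  k + cfg$dy_seal + cfg$h_seal
}

#' Locate the upper boundary of the cream layer
#'
#' Scans the axial gradient inside the cream-side half (rows at or beyond
#' `y_mid`) and returns the first cream row: the row just past the first
#' strict gradient exceedance, plus the displacement `dy_cream`.
#'
#' @param profile An [axial_profile()] of the capillary ROI.
#' @param y_mid Axial midpoint row where the cream-side half begins.
#' @param cfg A [seg_config()].
#' @return Axial row index of the first cream row (0-based).
#' @export
locate_cream_start <- function(profile, y_mid, cfg = seg_config()) {
  k <- first_crossing(profile$gradient, cfg$grad_thresh, y_mid,
                      length(profile$gradient))
  if (is.na(k)) stop("interface not found: no gradient exceedance in the cream region")
  k + 1L + cfg$dy_cream
}

#' Locate the lower boundary of the cream layer
#'
#' First strict gradient exceedance past the cream start (the cream to
#' end-seal/air interface), plus the allowance `h_cream`. The scan starts
#' two rows past the cream start so that residual gradients of the
#' serum/cream meniscus do not masquerade as the cream end. When no
#' exceedance exists (incomplete filling reaching the ROI edge) the ROI's
#' far edge is returned and flagged via the `"fallback"` attribute.
#'
#' @param profile An [axial_profile()] of the capillary ROI.
#' @param y_cream_start Axial row of the first cream row.
#' @param cfg A [seg_config()].
#' @return Axial row index of the last cream row (0-based), with attribute
#'   `fallback = TRUE` when the ROI edge was used.
#' @export
locate_cream_end <- function(profile, y_cream_start, cfg = seg_config()) {
  k <- first_crossing(profile$gradient, cfg$grad_thresh, y_cream_start + 2L,
                      length(profile$gradient))
  if (is.na(k)) {
    out <- length(profile$values) - 1L
    attr(out, "fallback") <- TRUE
    return(out)
  }
  out <- k + cfg$h_cream
  attr(out, "fallback") <- FALSE
  out
}

## Minimum-area (rotated) rectangle of a point set by rotating calipers on
## its convex hull. Pixel centers are unit-square centers, so each extent
## gains +1. Returns c(w, h).
min_area_rect <- function(pts) {
  pts <- unique(as.matrix(pts))
  if (nrow(pts) == 1L) return(c(w = 1, h = 1))
  hull <- pts[grDevices::chull(pts), , drop = FALSE]
  if (nrow(hull) < 3L) {                      # collinear set
    d <- hull[2, ] - hull[1, ]
    u <- d / sqrt(sum(d^2))
    proj <- pts %*% u
    return(c(w = diff(range(proj)) + 1, h = 1))
  }
  best <- NULL; best_area <- Inf
  n <- nrow(hull)
  for (i in seq_len(n)) {
    e <- hull[i %% n + 1L, ] - hull[i, ]
    len <- sqrt(sum(e^2))
    if (len == 0) next
    u <- e / len
    v <- c(-u[2], u[1])
    w <- diff(range(hull %*% u)) + 1
    h <- diff(range(hull %*% v)) + 1
    if (w * h < best_area) { best_area <- w * h; best <- c(w = w, h = h) }
  }
  best
}

#' Phase height by minimum-area rectangle
#'
#' Masks pixels with gray value in `[lo, hi]` inside the ROI, takes the
#' dominant (largest) 8-connected component, fits the minimum-area rotated
#' rectangle to it and returns the longer rectangle side, which measures the
#' phase extent along the tube axis even under axial tilt.
#'
#' @param gray Gray image matrix.
#' @param r A [roi()] confining the phase.
#' @param lo,hi Inclusive gray range of the phase.
#' @return List with `height` (`max(w, h)` in px), and the fitted rectangle
#'   sides `rect_w`, `rect_h`.
#' @export
phase_height <- function(gray, r, lo, hi) {
  if (lo >= hi) stop("invalid range: need lo < hi")
  sub <- roi_pixels(gray, r)
  sel <- sub >= lo & sub <= hi
  if (!any(sel)) stop("phase not found: no pixel in gray range [", lo, ", ", hi, "]")
  lab <- label_components8(sel)
  counts <- tabulate(lab[lab > 0L])
  k <- which.max(counts)
  px <- which(lab == k, arr.ind = TRUE)
  rect <- min_area_rect(cbind(px[, 2] - 1L, px[, 1] - 1L))
  list(height = max(rect), rect_w = unname(rect[1]), rect_h = unname(rect[2]))
}

#' Adaptive vertical crop to the biological content
#'
#' Returns the sub-image holding only serum and cream: axial rows
#' `[y_seal_end + 1, y_cream_end - 1]` inclusive, across the capillary's
#' full width. No horizontal cropping beyond the ROI is applied.
#'
#' @param img Color image array.
#' @param boundaries A `phase_boundaries` list (see [segment_capillary()]),
#'   or any list with axial `y_seal_end` and `y_cream_end`.
#' @param r The capillary [roi()].
#' @param orientation Seal orientation, as in [seg_config()].
#' @return Color image array of the cropped region.
#' @export
adaptive_crop <- function(img, boundaries, r, orientation = c("bottom", "top")) {
  orientation <- match.arg(orientation)
  ax_lo <- boundaries$y_seal_end + 1L
  ax_hi <- boundaries$y_cream_end            # inclusive of y_cream_end - 1
  if (ax_hi <= ax_lo) stop("crop failed: empty vertical window")
  rr <- axial_to_image_roi(r, ax_lo, ax_hi, orientation)
  img[(rr$y_min + 1L):rr$y_max, (rr$x_min + 1L):rr$x_max, , drop = FALSE]
}

#' Segment a capillary image into its phases
#'
#' Full hierarchical segmentation: grayscale conversion, global
#' binarization, capillary ROI extraction, midpoint split, gradient-based
#' interface location, intensity-range phase heights by minimum-area
#' rectangle, and adaptive cropping. The serum height is measured inside
#' ROI3 (strictly between the seal end and the cream start); the cream
#' height inside the cream-side half. `h_t = h_s + h_c` and
#' `c = h_c / h_t`.
#'
#' @param img Color image array (`H x W x 3`, 8-bit).
#' @param cfg A [seg_config()].
#' @return List with components `boundaries` (class `phase_boundaries`:
#'   `y_base` image row of the axial origin, axial rows `y_mid`,
#'   `y_seal_end`, `y_cream_start`, `y_cream_end`, heights `h_s`, `h_c`,
#'   `h_t`, rectangle sides `rect_s`, `rect_c`), `roi`, `crop`, `c` (cream
#'   fraction) and `warnings` (character vector).
#' @export
segment_capillary <- function(img, cfg = seg_config()) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("segmentation stage '", name, "': ", conditionMessage(e), call. = FALSE))
  }
  warnings <- character()
  img <- stage("input", validate_color_image(img))
  gray <- stage("grayscale", to_grayscale(img))
  mask <- stage("binarize", binarize(gray, cfg$Tb))
  comp <- stage("roi", find_capillary_component(mask, cfg))
  r <- comp$roi
  h <- roi_height(r)
  if (h < 2L) stop("segmentation stage 'split': capillary ROI height < 2")
  y_mid <- h %/% 2L
  prof <- stage("profile", axial_profile(gray, r, seal_from = cfg$orientation,
                                         mask = comp$mask))
  y_seal_end <- stage("seal interface", locate_seal_end(prof, cfg, y_mid = y_mid))
  y_cream_start <- stage("cream interface", locate_cream_start(prof, y_mid, cfg))
  y_cream_end <- stage("cream end", locate_cream_end(prof, y_cream_start, cfg))
  if (isTRUE(attr(y_cream_end, "fallback")))
    warnings <- c(warnings, "cream end not detected; using ROI edge (incomplete filling?)")
  y_cream_end <- as.integer(y_cream_end)
  if (y_cream_start <= y_seal_end + 1L)
    stop("segmentation stage 'interfaces': cream start not beyond seal end")

  roi3 <- axial_to_image_roi(r, y_seal_end + 1L, y_cream_start,
                             cfg$orientation, label = "serum")
  roi2 <- axial_to_image_roi(r, y_mid, h, cfg$orientation, label = "cream")
  serum <- stage("serum height", phase_height(gray, roi3, cfg$Tmin_g, cfg$Tmax_g))
  cream <- stage("cream height", phase_height(gray, roi2, cfg$Tw + 1L, 255L))
  h_s <- serum$height; h_c <- cream$height
  h_t <- h_s + h_c
  crop <- stage("crop", adaptive_crop(img, list(y_seal_end = y_seal_end,
                                                y_cream_end = y_cream_end),
                                      r, cfg$orientation))
  boundaries <- structure(list(
    y_base = if (cfg$orientation == "bottom") r$y_max - 1L else r$y_min,
    y_mid = y_mid, y_seal_end = as.integer(y_seal_end),
    y_cream_start = as.integer(y_cream_start), y_cream_end = y_cream_end,
    h_s = h_s, h_c = h_c, h_t = h_t,
    rect_s = c(w = serum$rect_w, h = serum$rect_h),
    rect_c = c(w = cream$rect_w, h = cream$rect_h)),
    class = "phase_boundaries")
  list(boundaries = boundaries, roi = r, crop = crop,
       c = h_c / h_t, warnings = warnings)
}
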