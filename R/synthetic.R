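## Synthetic capillary renderer: labeled fixtures with the optical structure
## the segmentation assumes — a dark enclosure background, a sealed tube
## with stacked seal / serum / cream phases whose gray levels respect the
## segmentation thresholds, warm (gold) or cool channel gains, additive
## Gaussian sensor noise, axial tilt and incomplete filling.
##
## Ground truth is expressed in axial coordinates (0 at the seal-end
## extremity of the liquid column, increasing along the tube), matching the
## convention of segment_capillary(). Axial distances are invariant under
## the tilt rotation, so heights and the cream fraction carry over exactly.

ILLUM_GAINS <- list(
  ## per-channel gains (R, G, B), normalized so BT.601 luma is preserved,
  ## and a brightness factor for the high-intensity variants
  gold_low  = list(gain = c(1.25, 1.00, 0.35), brightness = 1.00),
  gold_high = list(gain = c(1.25, 1.00, 0.35), brightness = 1.35),
  blue      = list(gain = c(0.40, 1.08, 2.20), brightness = 1.00),
  yellow    = list(gain = c(1.15, 1.10, 0.20), brightness = 1.00))

#' Specification of one synthetic capillary scene
#'
#' Defaults reproduce the reference acquisition geometry: a 227-px liquid
#' column (serum 215 px, cream 12 px, cream fraction 12/227 = 0.0529) in a
#' 5-px-bore tube under gold low-intensity illumination, matching the
#' pixel-scale experimental means of the digital system.
#'
#' @param rows,cols Image size in pixels.
#' @param tube_width Inner tube width in px.
#' @param seal_height Seal plug height in px.
#' @param serum_height,cream_height Phase heights `h_s`, `h_c` in px.
#' @param seal_gray,serum_gray,cream_gray,background_gray Mean gray levels;
#'   serum must lie in the serum gray range, cream and seal above the
#'   intensity threshold, background at or below the binarization threshold.
#' @param tilt Axial tilt in degrees (positive = clockwise).
#' @param fill_fraction Filled fraction of the reference column, in (0, 1]
#'   (recorded; the heights carry the geometry).
#' @param noise_sigma Standard deviation of i.i.d. per-channel Gaussian
#'   sensor noise, a.u.
#' @param illumination `"gold_low"`, `"gold_high"`, `"blue"` or `"yellow"`.
#' @param seed Integer seed for the noise.
#' @param cfg A [seg_config()] supplying the thresholds the scene must
#'   respect.
#' @return A `capillary_spec` list.
#' @export
capillary_spec <- function(rows = 320, cols = 48, tube_width = 5,
                           seal_height = 30, serum_height = 215,
                           cream_height = 12,
                           seal_gray = 200, serum_gray = 60,
                           cream_gray = 150, background_gray = 10,
                           tilt = 0, fill_fraction = 1, noise_sigma = 4,
                           illumination = c("gold_low", "gold_high",
                                            "blue", "yellow"),
                           seed = 1, cfg = seg_config()) {
  illumination <- match.arg(illumination)
  spec <- list(rows = as.integer(rows), cols = as.integer(cols),
               tube_width = as.integer(tube_width),
               seal_height = as.integer(seal_height),
               serum_height = as.integer(serum_height),
               cream_height = as.integer(cream_height),
               seal_gray = seal_gray, serum_gray = serum_gray,
               cream_gray = cream_gray, background_gray = background_gray,
               tilt = tilt, fill_fraction = fill_fraction,
               noise_sigma = noise_sigma, illumination = illumination,
               seed = as.integer(seed))
  if (spec$serum_gray < cfg$Tmin_g || spec$serum_gray > cfg$Tmax_g)
    stop("invalid spec: serum_gray must lie in the serum range [",
         cfg$Tmin_g, ", ", cfg$Tmax_g, "]")
  if (spec$cream_gray <= cfg$Tw || spec$seal_gray <= cfg$Tw)
    stop("invalid spec: cream_gray and seal_gray must exceed Tw = ", cfg$Tw)
  if (spec$background_gray > cfg$Tb)
    stop("invalid spec: background_gray must not exceed Tb = ", cfg$Tb)
  ## >= 99% of background pixels must stay at or below Tb after noise
  ## (luma noise sd is ~0.676 * noise_sigma under BT.601 weights)
  if (spec$background_gray + 2.33 * 0.676 * spec$noise_sigma > cfg$Tb)
    stop("invalid spec: background + noise would cross the binarization threshold")
  if (spec$fill_fraction <= 0 || spec$fill_fraction > 1)
    stop("invalid spec: fill_fraction must lie in (0, 1]")
  if (spec$serum_height < 2L || spec$cream_height < 1L || spec$seal_height < 2L)
    stop("invalid spec: phase heights too small")
  col_len <- spec$seal_height + spec$serum_height + spec$cream_height
  t_rad <- abs(spec$tilt) * pi / 180
  if (col_len * cos(t_rad) + spec$tube_width * sin(t_rad) > spec$rows - 4L)
    stop("invalid spec: phase stack does not fit the image height")
  if (col_len * sin(t_rad) + spec$tube_width * cos(t_rad) > spec$cols - 4L)
    stop("invalid spec: tilted tube does not fit the image width")
  class(spec) <- "capillary_spec"
  spec
}

## Per-axial-row gray level of the liquid column, axial row 0 = seal bottom.
## Meniscus curvature is emulated as single blended rows at the liquid
## interfaces (on the seal side of the seal/serum interface and the cream
## side of the serum/cream and cream/air interfaces); the seal's outer end
## is sharp (a plasticine plug has no meniscus).
column_gray_profile <- function(spec) {
  blend <- function(inner, outer) 0.7 * inner + 0.3 * outer
  seal <- rep(spec$seal_gray, spec$seal_height)
  seal[spec$seal_height] <- blend(spec$seal_gray, spec$serum_gray)
  serum <- rep(spec$serum_gray, spec$serum_height)
  cream <- rep(spec$cream_gray, spec$cream_height)
  cream[1] <- blend(spec$cream_gray, spec$serum_gray)
  cream[spec$cream_height] <- blend(spec$cream_gray, spec$background_gray)
  c(seal, serum, cream)
}

#' Render a synthetic capillary image with ground truth
#'
#' Draws the axis-aligned phase stack at the specified gray levels with
#' single-row meniscus blends at the liquid interfaces, applies the
#' illumination's channel gains, rotates the scene by the tilt angle about
#' the image center (nearest-neighbor sampling, preserving 8-bit values),
#' and adds clamped per-channel Gaussian noise. Deterministic per seed.
#'
#' @param spec A [capillary_spec()].
#' @return List with `image` (`H x W x 3` integer array) and `truth`, a
#'   one-row data frame with axial interface rows (`y_seal_end`,
#'   `y_cream_start`, `y_cream_end`), heights `h_s`, `h_c`, `h_t`, the cream
#'   fraction `c = h_c / h_t` and the derived `F` (fat %) and `ED` (kcal/L).
#' @export
render_capillary <- function(spec) {
  if (!inherits(spec, "capillary_spec")) spec <- do.call(capillary_spec, spec)
  rows <- spec$rows; cols <- spec$cols
  col_len <- spec$seal_height + spec$serum_height + spec$cream_height
  prof <- column_gray_profile(spec)

  ## untilted scene: tube centered, seal at the bottom, margins split evenly
  x0 <- (cols - spec$tube_width) %/% 2L          # 0-based first tube column
  y_bottom <- rows - (rows - col_len) %/% 2L     # 0-based row below the seal
  ## axial row of image row y (untilted): a = y_bottom - 1 - y

  ## inverse nearest-neighbor rotation about the image center
  cy <- (rows - 1) / 2; cx <- (cols - 1) / 2
  t_rad <- spec$tilt * pi / 180
  gx <- matrix(rep(0:(cols - 1), each = rows), rows, cols) - cx
  gy <- matrix(rep(0:(rows - 1), times = cols), rows, cols) - cy
  sx <- round(cos(t_rad) * gx + sin(t_rad) * gy + cx)
  sy <- round(-sin(t_rad) * gx + cos(t_rad) * gy + cy)

  ax <- y_bottom - 1 - sy                        # axial row in source frame
  inside <- sx >= x0 & sx < x0 + spec$tube_width & ax >= 0 & ax < col_len
  gray_scene <- matrix(spec$background_gray, rows, cols)
  gray_scene[inside] <- prof[ax[inside] + 1L]

  il <- ILLUM_GAINS[[spec$illumination]]
  img <- array(0L, dim = c(rows, cols, 3L))
  set.seed(spec$seed)
  for (k in 1:3) {
    ch <- gray_scene * il$gain[k] * il$brightness
    if (spec$noise_sigma > 0)
      ch <- ch + stats::rnorm(length(ch), 0, spec$noise_sigma)
    ch <- floor(ch + 0.5)
    ch[ch < 0] <- 0; ch[ch > 255] <- 255
    img[, , k] <- as.integer(ch)
  }

  h_s <- spec$serum_height; h_c <- spec$cream_height
  h_t <- h_s + h_c
  cfrac <- h_c / h_t
  truth <- data.frame(
    y_seal_end = spec$seal_height - 1L,
    y_cream_start = spec$seal_height + h_s,
    y_cream_end = spec$seal_height + h_s + h_c - 1L,
    h_s = h_s, h_c = h_c, h_t = h_t,
    c = cfrac, F = fat_percent(cfrac), ED = energy_density(cfrac),
    tilt = spec$tilt, fill = spec$fill_fraction, seed = spec$seed)
  list(image = img, truth = truth)
}

#' Generate a labeled synthetic dataset
#'
#' Draws cream fractions, tilts and fill fractions uniformly from the
#' stated ranges, renders one capillary per draw and returns the images
#' with their ground-truth labels. The defaults span the validated clinical
#' range of cream fractions. The realized cream fraction after rounding the
#' phase heights to whole pixels is what the labels carry.
#'
#' @param n Number of images (>= 1).
#' @param c_range Cream fraction range; default `c(0.0429, 0.0663)`.
#' @param tilt_range Tilt range in degrees; default `c(-5, 5)`.
#' @param fill_range Fill fraction range; default `c(0.7, 1)`.
#' @param noise_sigma Sensor noise sd, a.u.; default 4.
#' @param seed Master seed; per-image seeds and draws derive from it.
#' @param illumination Illumination mode for all images.
#' @param dir Optional directory: when given, writes `capillary_####.png`
#'   images and a `labels.csv` there.
#' @param h_t_ref Reference full-column height in px at `fill = 1`;
#'   default 227.
#' @return List with `images` (list of arrays), `labels` (data frame with
#'   `image_id`, `h_s`, `h_c`, `h_t`, `c`, `F`, `ED`, `tilt`, `fill`,
#'   `seed`) and `specs`.
#' @export
generate_dataset <- function(n, c_range = c(0.0429, 0.0663),
                             tilt_range = c(-5, 5), fill_range = c(0.7, 1),
                             noise_sigma = 4, seed = 1,
                             illumination = "gold_low", dir = NULL,
                             h_t_ref = 227) {
  if (n < 1) stop("n must be at least 1")
  for (rg in list(c_range, tilt_range, fill_range))
    if (length(rg) != 2L || rg[1] > rg[2]) stop("ranges must be (lo, hi) with lo <= hi")
  set.seed(seed)
  c_draw <- stats::runif(n, c_range[1], c_range[2])
  tilt_draw <- stats::runif(n, tilt_range[1], tilt_range[2])
  fill_draw <- stats::runif(n, fill_range[1], fill_range[2])
  seeds <- sample.int(.Machine$integer.max %/% 2L, n)

  images <- vector("list", n)
  specs <- vector("list", n)
  labels <- vector("list", n)
  for (i in seq_len(n)) {
    h_t <- max(10L, as.integer(round(fill_draw[i] * h_t_ref)))
    h_c <- max(1L, as.integer(round(c_draw[i] * h_t)))
    spec <- capillary_spec(serum_height = h_t - h_c, cream_height = h_c,
                           tilt = tilt_draw[i], fill_fraction = fill_draw[i],
                           noise_sigma = noise_sigma,
                           illumination = illumination, seed = seeds[i])
    out <- render_capillary(spec)
    images[[i]] <- out$image
    specs[[i]] <- spec
    labels[[i]] <- cbind(image_id = sprintf("capillary_%04d", i), out$truth)
  }
  labels <- do.call(rbind, labels)
  rownames(labels) <- NULL
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    for (i in seq_len(n))
      write_capillary_image(images[[i]],
                            file.path(dir, paste0(labels$image_id[i], ".png")))
    utils::write.csv(labels[setdiff(names(labels),
                                    c("y_seal_end", "y_cream_start",
                                      "y_cream_end"))],
                     file.path(dir, "labels.csv"), row.names = FALSE)
  }
  list(images = images, labels = labels, specs = specs)
}
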