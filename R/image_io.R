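#' Read an 8-bit color capillary image
#'
#' Reads a PNG, TIFF or JPEG file into the package's working representation:
#' an integer array `[rows, cols, 3]` with values in `[0, 255]`. Grayscale
#' files are replicated across the three channels; an alpha channel, if
#' present, is dropped.
#'
#' @param path Path to a `.png`, `.tif`/`.tiff`, `.jpg`/`.jpeg` file.
#' @return Integer array `H x W x 3` of 8-bit intensities.
#' @export
read_capillary_image <- function(path) {
  if (!file.exists(path)) stop("image file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    png  = png::readPNG(path),
    tif  = ,
    tiff = tiff::readTIFF(path),
    jpg  = ,
    jpeg = {
      if (!requireNamespace("jpeg", quietly = TRUE))
        stop("the 'jpeg' package is required to read JPEG files")
      jpeg::readJPEG(path)
    },
    stop("unsupported image format: .", ext, " (use PNG, TIFF or JPEG)")
  )
  as_color_image(raw)
}

#' Write a color image as PNG
#'
#' @param img Integer array `H x W x 3`, values in `[0, 255]`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_capillary_image <- function(img, path) {
  img <- validate_color_image(img)
  png::writePNG(img / 255, target = path)
  invisible(path)
}

## Coerce readers' output ([0,1] doubles, 1/2/3/4 channels) to H x W x 3 ints.
as_color_image <- function(raw) {
  if (is.matrix(raw)) raw <- array(rep(raw, 3L), dim = c(dim(raw), 3L))
  if (length(dim(raw)) != 3L) stop("invalid image: expected 2-D or 3-D data")
  nc <- dim(raw)[3]
  if (nc == 1L) raw <- array(rep(raw[, , 1L], 3L), dim = c(dim(raw)[1:2], 3L))
  if (nc == 2L) raw <- array(rep(raw[, , 1L], 3L), dim = c(dim(raw)[1:2], 3L))
  if (nc >= 4L) raw <- raw[, , 1:3, drop = FALSE]
  if (max(raw) <= 1) raw <- raw * 255
  storage.mode(raw) <- "integer"
  validate_color_image(raw)
}

validate_color_image <- function(img) {
  if (!is.array(img) || length(dim(img)) != 3L || dim(img)[3] != 3L)
    stop("invalid color image: need an H x W x 3 array")
  if (dim(img)[1] < 2L || dim(img)[2] < 1L)
    stop("invalid color image: height must be >= 2 and width >= 1")
  if (anyNA(img) || min(img) < 0 || max(img) > 255)
    stop("invalid color image: channel values must lie in [0, 255]")
  storage.mode(img) <- "integer"
  img
}

validate_gray_image <- function(gray) {
  if (!is.matrix(gray)) stop("invalid gray image: need an H x W matrix")
  if (anyNA(gray) || min(gray) < 0 || max(gray) > 255)
    stop("invalid gray image: values must lie in [0, 255]")
  gray
}
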