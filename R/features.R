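## Intensity-histogram feature vectors of the cropped sample image.
##
## For each channel k in {R, G, B, Gray} the 256-bin histogram
## H_k(i) = #{(x, y) : I_k(x, y) = i} is computed; the feature vector is
## the concatenation R || G || B (|| Gray). Frequency normalization divides
## each 256-block by the crop's pixel count, making features comparable
## across crops of different height (the default, since the crop height
## varies with the cream fraction).

#' 256-bin intensity histogram of one channel
#'
#' @param channel Integer matrix (or vector) of 8-bit values in `[0, 255]`.
#' @return Numeric vector of length 256; element `i + 1` counts pixels of
#'   intensity `i`.
#' @export
channel_histogram <- function(channel) {
  v <- as.integer(channel)
  if (!length(v)) stop("empty input: channel has no pixels")
  if (anyNA(v) || min(v) < 0 || max(v) > 255)
    stop("channel values must lie in [0, 255]")
  as.numeric(tabulate(v + 1L, nbins = 256L))
}

feature_block_names <- function(mode) {
  bins <- 0:255
  switch(mode,
    gray = paste0("Gray_", bins),
    rgb = c(paste0("R_", bins), paste0("G_", bins), paste0("B_", bins)),
    combined = c(paste0("R_", bins), paste0("G_", bins), paste0("B_", bins),
                 paste0("Gray_", bins)),
    stop("unknown feature mode: '", mode, "' (use gray, rgb or combined)"))
}

#' Histogram feature vector of a cropped sample image
#'
#' Concatenated per-channel histograms in the fixed order R, G, B, Gray.
#' `mode = "gray"` yields 256 features, `"rgb"` 768 and `"combined"` 1024.
#' The Gray block is recomputed from the crop with the same BT.601 luma as
#' the segmentation.
#'
#' @param crop Color image array (`H x W x 3`, 8-bit), typically the output
#'   of [adaptive_crop()].
#' @param mode `"gray"`, `"rgb"` or `"combined"`.
#' @param normalization `"frequency"` (default; each 256-block sums to 1) or
#'   `"counts"` (each block sums to the crop's pixel count).
#' @return Named numeric vector with attributes `mode` and `normalization`.
#' @export
feature_vector <- function(crop, mode = c("combined", "rgb", "gray"),
                           normalization = c("frequency", "counts")) {
  mode <- match.arg(mode)
  normalization <- match.arg(normalization)
  crop <- validate_color_image(crop)
  blocks <- switch(mode,
    gray = list(channel_histogram(to_grayscale(crop))),
    rgb = list(channel_histogram(crop[, , 1]),
               channel_histogram(crop[, , 2]),
               channel_histogram(crop[, , 3])),
    combined = list(channel_histogram(crop[, , 1]),
                    channel_histogram(crop[, , 2]),
                    channel_histogram(crop[, , 3]),
                    channel_histogram(to_grayscale(crop))))
  if (normalization == "frequency") {
    npx <- prod(dim(crop)[1:2])
    blocks <- lapply(blocks, function(b) b / npx)
  }
  out <- unlist(blocks, use.names = FALSE)
  names(out) <- feature_block_names(mode)
  attr(out, "mode") <- mode
  attr(out, "normalization") <- normalization
  out
}

#' Feature table for a set of crops
#'
#' One row per image with stable column names (`R_0` .. `Gray_255`), plus an
#' optional target column `c` of ground-truth cream fractions.
#'
#' @param crops List of color image arrays.
#' @param mode Feature mode, as in [feature_vector()].
#' @param labels Optional numeric vector of cream fractions, one per crop.
#' @param normalization As in [feature_vector()].
#' @return Data frame of features (and `c` when labels are supplied).
#' @export
feature_table <- function(crops, mode = c("combined", "rgb", "gray"),
                          labels = NULL,
                          normalization = c("frequency", "counts")) {
  mode <- match.arg(mode)
  normalization <- match.arg(normalization)
  cols <- feature_block_names(mode)
  if (!length(crops)) {
    out <- as.data.frame(matrix(numeric(), 0, length(cols),
                                dimnames = list(NULL, cols)))
    if (!is.null(labels)) out$c <- numeric()
    return(out)
  }
  if (!is.null(labels) && length(labels) != length(crops))
    stop("labels must have one entry per crop")
  rows <- lapply(crops, feature_vector, mode = mode,
                 normalization = normalization)
  out <- as.data.frame(do.call(rbind, rows))
  names(out) <- cols
  if (!is.null(labels)) out$c <- as.numeric(labels)
  rownames(out) <- NULL
  out
}
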