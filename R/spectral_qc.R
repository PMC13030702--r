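## Illumination quality control: pixel-intensity distribution statistics and
## dynamic range for an acquisition configuration. Intensities are pooled
## across the R, G and B channels ("pixel value (a.u.)").

#' Randomly subsample pixel intensities from an image
#'
#' Draws `n` intensities uniformly with replacement from all channel values
#' of the image; reproducible for a fixed seed.
#'
#' @param img Color image array.
#' @param n Number of subsamples; default 30000.
#' @param seed Optional integer seed.
#' @return Integer vector of length `n`.
#' @export
sample_pixels <- function(img, n = 30000, seed = NULL) {
  img <- validate_color_image(img)
  if (n < 1) stop("n must be at least 1")
  pool <- as.vector(img)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  pool[sample.int(length(pool), n, replace = TRUE)]
}

#' Intensity distribution statistics
#'
#' Quartiles (linear interpolation between order statistics), extrema and
#' dynamic range `dr = max - min` of an intensity sample.
#'
#' @param sample Numeric vector of intensities (a.u.).
#' @return List of class `intensity_stats` with `q1`, `q2`, `q3`, `min`,
#'   `max`, `dr`, `n`.
#' @export
intensity_stats <- function(sample) {
  if (!length(sample)) stop("empty sample")
  q <- unname(stats::quantile(sample, c(0.25, 0.5, 0.75), type = 7))
  structure(list(q1 = q[1], q2 = q[2], q3 = q[3],
                 min = min(sample), max = max(sample),
                 dr = max(sample) - min(sample),
                 n = length(sample)),
            class = "intensity_stats")
}

#' Rank illumination conditions by dynamic range
#'
#' Conditions are sorted by decreasing dynamic range; ties are broken in
#' favor of the lower minimum (deeper noise floor).
#'
#' @param stats_by_condition Named list of [intensity_stats()] objects, or a
#'   data frame with columns `condition`, `q1`, `q2`, `q3`, `min`, `max`,
#'   `dr` (and optionally `n`).
#' @return Data frame mirroring the QC report columns, best condition first.
#' @export
compare_conditions <- function(stats_by_condition) {
  if (is.data.frame(stats_by_condition)) {
    df <- stats_by_condition
  } else {
    if (!length(stats_by_condition)) stop("need at least one condition")
    df <- do.call(rbind, lapply(names(stats_by_condition), function(nm) {
      s <- stats_by_condition[[nm]]
      data.frame(condition = nm, q1 = s$q1, q2 = s$q2, q3 = s$q3,
                 min = s$min, max = s$max, dr = s$dr, n = s$n)
    }))
  }
  df[order(-df$dr, df$min), , drop = FALSE]
}
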