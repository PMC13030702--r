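## Creamatocrit conversion and uncertainty budgets.
##
## Fat percentage and energy density are linear in the cream fraction
## c = h_c / h_t:
##   F  = (2950 / 73) * c          [%]
##   ED = 6680 * c + 290           [kcal/L]
## Worst-case first-order propagation of the instrument resolution dh
## (0.5 mm half-division for an analog caliper, 1 px for the camera) gives
##   dF  = (2950 / 73) * (dh / h_t) * (1 + c)
##   dED = 6680 * (dh / h_t) * (1 + c),
## so the dimensionless fraction makes the pixel-domain measurement
## self-calibrating: no px-to-mm conversion enters any derived quantity.

FAT_COEF <- 2950 / 73     # 40.41: fat % per unit cream fraction
ED_SLOPE <- 6680          # kcal/L per unit cream fraction
ED_OFFSET <- 290          # kcal/L at c = 0

check_fraction <- function(c) {
  if (any(!is.finite(c)) || any(c < 0) || any(c > 1))
    stop("cream fraction must lie in [0, 1]")
  c
}

#' Fat percentage from the cream fraction
#'
#' `F = (2950 / 73) * c`; the prefactor rounds to 40.41.
#'
#' @param c Cream fraction(s) in `[0, 1]`.
#' @return Fat content in percent.
#' @export
fat_percent <- function(c) FAT_COEF * check_fraction(c)

#' Energy density from the cream fraction
#'
#' `ED = 6680 * c + 290` kcal/L.
#'
#' @inheritParams fat_percent
#' @return Energy density in kcal/L.
#' @export
energy_density <- function(c) ED_SLOPE * check_fraction(c) + ED_OFFSET

check_positive <- function(x, what) {
  if (any(!is.finite(x)) || any(x <= 0)) stop(what, " must be positive")
  x
}

#' Absolute fat uncertainty from instrument resolution
#'
#' Worst-case propagation `dF = (2950 / 73) * (delta_h / h_t) * (1 + c)`.
#' `delta_h` and `h_t` must share a unit (mm for the analog caliper,
#' px for the digital system); the unit cancels.
#'
#' @param c Cream fraction(s) in `[0, 1]`.
#' @param h_t Total column height (mm or px), positive.
#' @param delta_h Instrument resolution in the same unit, positive.
#' @return Absolute fat uncertainty in percent.
#' @export
fat_uncertainty <- function(c, h_t, delta_h) {
  check_fraction(c); check_positive(h_t, "h_t"); check_positive(delta_h, "delta_h")
  FAT_COEF * (delta_h / h_t) * (1 + c)
}

#' Absolute energy-density uncertainty from instrument resolution
#'
#' `dED = 6680 * (delta_h / h_t) * (1 + c)` kcal/L.
#'
#' @inheritParams fat_uncertainty
#' @return Absolute energy-density uncertainty in kcal/L.
#' @export
energy_uncertainty <- function(c, h_t, delta_h) {
  check_fraction(c); check_positive(h_t, "h_t"); check_positive(delta_h, "delta_h")
  ED_SLOPE * (delta_h / h_t) * (1 + c)
}

#' Relative error in percent
#'
#' @param delta Absolute uncertainty.
#' @param mean Mean value of the quantity, same unit, positive.
#' @return `100 * delta / mean`.
#' @export
relative_error <- function(delta, mean) {
  check_positive(mean, "mean")
  100 * delta / mean
}

#' Relative error improvement
#'
#' Percentage reduction of the relative error achieved by the digital
#' system over the analog benchmark:
#' `(1 - digital_rel / analog_rel) * 100`.
#'
#' @param analog_rel Analog relative error in percent, positive.
#' @param digital_rel Digital relative error in percent.
#' @return Improvement in percent (at most 100).
#' @export
error_improvement <- function(analog_rel, digital_rel) {
  check_positive(analog_rel, "analog_rel")
  (1 - digital_rel / analog_rel) * 100
}

#' Uncertainty band over a grid of cream fractions
#'
#' Tabulates fat, energy density and their absolute uncertainties for each
#' cream fraction at a fixed column height and instrument resolution.
#'
#' @param c_grid Cream fractions in `[0, 1]`.
#' @param h_t Total column height, positive.
#' @param delta_h Instrument resolution, same unit as `h_t`.
#' @param mode Label stored in the `mode` column: `"analog"` or `"digital"`.
#' @return Data frame with columns `c`, `F`, `dF`, `ED`, `dED`, `mode`.
#' @export
uncertainty_band <- function(c_grid, h_t, delta_h,
                             mode = c("digital", "analog")) {
  mode <- match.arg(mode)
  if (!length(c_grid))
    return(data.frame(c = numeric(), F = numeric(), dF = numeric(),
                      ED = numeric(), dED = numeric(),
                      mode = character()))
  data.frame(
    c = c_grid,
    F = fat_percent(c_grid),
    dF = fat_uncertainty(c_grid, h_t, delta_h),
    ED = energy_density(c_grid),
    dED = energy_uncertainty(c_grid, h_t, delta_h),
    mode = mode)
}
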