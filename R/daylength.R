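#' Civil daylength from latitude and day of year
#'
#' Photoperiod in hours from the standard CBM day-length model (Forsythe et
#' al. 1995): the revolution-angle parameterization of solar declination
#' with "day" defined as the period during which the solar elevation exceeds
#' -0.8333 degrees (atmospheric refraction plus the apparent solar radius,
#' the sunrise/sunset-table convention).
#'
#' Negative days of year index the previous calendar year (day 0 is 31
#' December of the previous year) and are mapped back onto 1..366 before
#' evaluation, so driver windows spanning the previous autumn can be filled
#' directly.
#'
#' @param latitude degrees north, in \[-90, 90\].
#' @param doy integer day(s) of year; values outside 1..366 are wrapped.
#' @param elev_deg solar elevation threshold in degrees defining "day";
#'   default -0.8333 (civil daylength). Exposed so alternate threshold-angle
#'   conventions can be swapped in.
#' @return daylength in hours, in \[0, 24\]; vectorized over `doy`.
#' @examples
#' compute_daylength(47.5, 172) # near-solstice, ~16 h
#' compute_daylength(0, 1:365)  # ~12 h year-round at the equator
#' @export
compute_daylength <- function(latitude, doy, elev_deg = -0.8333) {
  if (any(!is.finite(latitude)) || any(latitude < -90 | latitude > 90))
    stop("latitude must lie in [-90, 90]")
  d <- ((round(doy) - 1) %% 366) + 1
  theta <- 0.2163108 + 2 * atan(0.9671396 * tan(0.00860 * (d - 186)))
  decl <- asin(0.39795 * cos(theta))
  phi <- latitude * pi / 180
  p <- -elev_deg * pi / 180 # Forsythe's daylength coefficient
  cosw <- (sin(p) + sin(phi) * sin(decl)) / (cos(phi) * cos(decl))
  cosw <- pmin(pmax(cosw, -1), 1)
  24 - 24 / pi * acos(cosw)
}

#' Saturation vapour pressure (Tetens formula)
#'
#' @param t_air air temperature, degrees C.
#' @return saturation vapour pressure in kPa.
#' @export
saturation_vp <- function(t_air) {
  0.6108 * exp(17.27 * t_air / (t_air + 237.3))
}

#' Vapour pressure deficit from temperature and relative humidity
#'
#' VPD = e_sat(T) * (1 - RH/100), with e_sat from [saturation_vp()].
#'
#' @param t_air air temperature, degrees C.
#' @param relative_humidity percent, in \[0, 100\].
#' @return VPD in kPa (>= 0; exactly 0 at saturation).
#' @export
compute_vpd <- function(t_air, relative_humidity) {
  if (any(relative_humidity < 0 | relative_humidity > 100, na.rm = TRUE))
    stop("relative_humidity must lie in [0, 100]")
  pmax(saturation_vp(t_air) * (1 - relative_humidity / 100), 0)
}
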