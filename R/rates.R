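#' Daily response-rate building blocks
#'
#' The accumulation models are assembled from a small set of daily response
#' functions of temperature, photoperiod and vapour pressure deficit. These
#' are exported both for reuse and so each can be verified in isolation.
#'
#' @param T temperature, degC (vector or matrix).
#' @param T_base base temperature, degC.
#' @name rates
NULL

#' @describeIn rates growing-degree-day forcing, `max(T - T_base, 0)`.
#' @export
forcing_rate_linear <- function(T, T_base) pmax(T - T_base, 0)

#' @describeIn rates sigmoid forcing `1/(1 + exp(-b_f (T - c_f)))`,
#'   strictly increasing in `T`; `b_f > 0` is the slope, `c_f` the midpoint.
#' @param b_f,c_f sigmoid slope (> 0) and midpoint (degC).
#' @export
forcing_rate_sigmoid <- function(T, b_f, c_f) 1 / (1 + exp(-b_f * (T - c_f)))

#' @describeIn rates triangular chilling response: 0 outside
#'   `(T_min, T_max)`, rising linearly to 1 at `T_opt`, falling linearly back
#'   to 0 at `T_max`. Requires `T_min < T_opt < T_max`.
#' @param T_min,T_opt,T_max triangle foot, apex and upper foot (degC).
#' @export
chilling_rate_triangular <- function(T, T_min, T_opt, T_max) {
  if (!(T_min < T_opt && T_opt < T_max))
    stop("chilling triangle requires T_min < T_opt < T_max")
  up <- (T - T_min) / (T_opt - T_min)
  dn <- (T_max - T) / (T_max - T_opt)
  r <- pmin(up, dn)
  r[] <- pmin(pmax(r, 0), 1)
  r
}

#' @describeIn rates bell-shaped chilling response
#'   `1/(1 + exp(a_c (T - c_c)^2 + b_c (T - c_c)))`, unimodal in `T` with
#'   value 0.5 at `T = c_c`; `a_c > 0`.
#' @param a_c,b_c,c_c bell curvature (> 0), skew, and centre (degC).
#' @export
chilling_rate_bell <- function(T, a_c, b_c, c_c) {
  d <- T - c_c
  1 / (1 + exp(a_c * d * d + b_c * d))
}

#' @describeIn rates photoperiod multiplier on daily forcing: `"PTT"` variant
#'   scales by `L/24`; `"M1"` variant by `(L/10)^k` (unity at a 10 h day).
#' @param L daylength, hours.
#' @param variant `"PTT"` or `"M1"`.
#' @param k exponent for the M1 variant.
#' @export
photoperiod_multiplier <- function(L, variant = c("PTT", "M1"), k = 1) {
  variant <- match.arg(variant)
  if (variant == "PTT") L / 24 else (L / 10)^k
}

#' @describeIn rates autumn cold accumulation: `"linear"` form
#'   `max(T_base - T, 0)` (chilling degree days); `"sigmoid"` form
#'   `1/(1 + exp(b_s (T - c_s)))`, decreasing in `T`.
#' @param form `"linear"` or `"sigmoid"`.
#' @param b_s,c_s cold-sigmoid slope (> 0) and midpoint (degC).
#' @export
cold_rate <- function(T, form = c("linear", "sigmoid"), T_base = NULL,
                      b_s = NULL, c_s = NULL) {
  form <- match.arg(form)
  if (form == "linear") pmax(T_base - T, 0)
  else 1 / (1 + exp(b_s * (T - c_s)))
}

#' CO2 offset on the senescence requirement
#'
#' Elevated atmospheric CO2 enters the autumn models as an offset that lowers
#' the accumulated-cold requirement, letting senescence occur with less
#' forcing: `F_eff = max(F_star - c_co2 * max(co2 - CO2_ref, 0),
#' 0.05 F_star)`. At or below the reference concentration the requirement is
#' unchanged; the 5% floor keeps the requirement positive.
#'
#' @param F_star base requirement.
#' @param c_co2 offset per ppm above reference, >= 0.
#' @param co2_mean growing-season mean CO2 of the enclosure-year, ppm.
#' @param co2_ref reference concentration, default 400 ppm.
#' @return effective requirement(s), monotone non-increasing in `co2_mean`.
#' @export
co2_threshold_offset <- function(F_star, c_co2, co2_mean, co2_ref = 400) {
  if (any(c_co2 < 0)) stop("c_co2 must be >= 0")
  pmax(F_star - c_co2 * pmax(co2_mean - co2_ref, 0), 0.05 * F_star)
}

.ramp <- function(x, lo, hi) pmin(pmax((x - lo) / (hi - lo), 0), 1)
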