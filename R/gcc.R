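#' Daily greenness series
#'
#' A `gcc_series` is a data frame with columns `doy` (strictly increasing
#' integer axis), `gcc` (green chromatic coordinate, in (0, 1)) and
#' `snow_flag` (logical; days with snow contamination, which depresses the
#' greenness signal and are excluded from analysis). Attributes `enclosure`
#' and `roi` (DN/EN/SH) identify the source.
#'
#' @param doy integer day-of-year axis.
#' @param gcc greenness values in (0, 1).
#' @param snow_flag logical vector, default all `FALSE`.
#' @param enclosure,roi identifiers.
#' @return a `gcc_series` data frame.
#' @export
gcc_series <- function(doy, gcc, snow_flag = rep(FALSE, length(doy)),
                       enclosure = NA_character_, roi = NA_character_) {
  stopifnot(length(gcc) == length(doy), length(snow_flag) == length(doy))
  if (any(diff(doy) <= 0)) stop("doy axis must be strictly increasing")
  if (any(gcc <= 0 | gcc >= 1, na.rm = TRUE))
    stop("gcc values must lie strictly within (0, 1)")
  out <- data.frame(doy = as.integer(doy), gcc = as.numeric(gcc),
                    snow_flag = as.logical(snow_flag))
  attr(out, "enclosure") <- enclosure
  attr(out, "roi") <- roi
  class(out) <- c("gcc_series", "data.frame")
  out
}

#' Exclude snow-contaminated days from a greenness series
#'
#' Removes the listed days (plus any already flagged) from the usable set.
#' Flags that reference days absent from the axis raise a warning, not an
#' error.
#'
#' @param series a [gcc_series()].
#' @param flags integer days of year to exclude (may be empty).
#' @return the series with flagged days removed; axis order preserved.
#' @export
exclude_snow_days <- function(series, flags = integer()) {
  absent <- setdiff(flags, series$doy)
  if (length(absent))
    warning("snow flags reference days absent from the series: ",
            paste(head(absent, 5), collapse = ", "))
  drop <- series$snow_flag | series$doy %in% flags
  out <- series[!drop, , drop = FALSE]
  attributes(out)[c("enclosure", "roi")] <- attributes(series)[c("enclosure", "roi")]
  class(out) <- class(series)
  out
}

#' Three-day 90th-percentile greenness composite
#'
#' Composites the usable (non-snow, non-missing) greenness observations with
#' a moving 90th percentile over a centred window (default 3 days), the
#' smoothing applied to camera greenness before transition-date estimation.
#' The percentile uses the linear-interpolation definition
#' (`quantile(..., type = 7)`). Window positions with no usable observation
#' are filled by linear interpolation along the day axis.
#'
#' @param series a [gcc_series()].
#' @param window odd window width in days, default 3.
#' @return a `seasonal_curve`: list with `doy`, `gcc90` (composite),
#'   `baseline` (seasonal minimum), `amplitude` (max - min),
#'   `threshold_value` (baseline + 0.25 amplitude) and `residual_sd`
#'   (SD of raw minus composite over usable days, used for the heuristic
#'   confidence interval).
#' @export
composite_90th <- function(series, window = 3) {
  usable <- !series$snow_flag & !is.na(series$gcc)
  if (sum(usable) < window) stop("empty series: fewer usable days than the window")
  doy <- series$doy
  half <- (window - 1) / 2
  g <- ifelse(usable, series$gcc, NA_real_)
  n <- length(doy)
  comp <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    sel <- which(doy >= doy[i] - half & doy <= doy[i] + half)
    v <- g[sel]
    v <- v[!is.na(v)]
    if (length(v)) comp[i] <- quantile(v, 0.9, type = 7, names = FALSE)
  }
  if (anyNA(comp)) {
    ok <- !is.na(comp)
    comp <- approx(doy[ok], comp[ok], xout = doy, rule = 2)$y
  }
  baseline <- min(comp)
  amplitude <- max(comp) - baseline
  res <- series$gcc[usable] - comp[usable]
  structure(list(doy = doy, gcc90 = comp, baseline = baseline,
                 amplitude = amplitude,
                 threshold_value = baseline + 0.25 * amplitude,
                 residual_sd = if (length(res) > 2) sd(res) else 0),
            class = "seasonal_curve")
}

# first upward crossing of `thr` on the rising limb (seasonal minimum ->
# peak); linear interpolation between the bracketing days. NA if none.
.cross_up <- function(doy, y, thr, from, to) {
  if (to <= from) return(NA_real_)
  for (i in from:(to - 1)) {
    if (y[i] < thr && y[i + 1] >= thr) {
      f <- (thr - y[i]) / (y[i + 1] - y[i])
      return(doy[i] + f * (doy[i + 1] - doy[i]))
    }
  }
  NA_real_
}

.cross_down_last <- function(doy, y, thr, from, to) {
  out <- NA_real_
  if (to <= from) return(out)
  for (i in from:(to - 1)) {
    if (y[i] >= thr && y[i + 1] < thr) {
      f <- (y[i] - thr) / (y[i] - y[i + 1])
      out <- doy[i] + f * (doy[i + 1] - doy[i])
    }
  }
  out
}

#' Extract a transition date from a seasonal greenness curve
#'
#' Finds the day on which the composited greenness crosses 25% of its
#' seasonal amplitude: in spring, the first upward crossing on the rising
#' limb (after the seasonal minimum, before the peak); in autumn, the last
#' downward crossing on the falling limb (after the peak). The crossing day
#' is linearly interpolated between the bracketing days. A heuristic 90%
#' interval is attached by re-crossing the threshold with the curve shifted
#' by +/- 1.645 residual SDs. When the curve never crosses the threshold a
#' no-transition sentinel (`doy = NA`) is returned rather than an error.
#'
#' @param curve a `seasonal_curve` from [composite_90th()].
#' @param season `"spring"` or `"autumn"`.
#' @return list with `doy` (fractional day, NA when no transition),
#'   `ci_lower`, `ci_upper`, `season`, `threshold_value`.
#' @export
extract_transitions <- function(curve, season = c("spring", "autumn")) {
  season <- match.arg(season)
  if (curve$amplitude <= 0) stop("seasonal amplitude must be positive")
  doy <- curve$doy; y <- curve$gcc90
  thr <- curve$threshold_value
  peak <- which.max(y)
  shift <- 1.645 * curve$residual_sd
  cross <- function(th) {
    if (season == "spring") {
      lo <- which.min(y[1:peak])
      .cross_up(doy, y, th, lo, peak)
    } else {
      hi <- peak - 1L + which.min(y[peak:length(y)])
      .cross_down_last(doy, y, th, peak, hi)
    }
  }
  d <- cross(thr)
  if (is.na(d))
    return(list(doy = NA_real_, ci_lower = NA_real_, ci_upper = NA_real_,
                season = season, threshold_value = thr,
                status = "no_transition"))
  ci <- sort(c(cross(thr - shift), cross(thr + shift)))
  if (length(ci) < 2 || anyNA(ci)) ci <- c(d, d)
  list(doy = d, ci_lower = ci[1], ci_upper = ci[2], season = season,
       threshold_value = thr, status = "ok")
}

#' Read a greenness table
#'
#' Reads a CSV with columns `enclosure`, `roi`, and either `date`
#' (ISO-8601) or `doy` + `year`, plus `gcc` (a `gcc_90` column is honoured
#' in preference to `gcc` when present, for compatibility with camera-network
#' summary products) and optionally `snow_flag`.
#'
#' @param path CSV file.
#' @return named list of [gcc_series()], one per (enclosure, roi, year),
#'   names `"<enclosure>.<roi>.<year>"`.
#' @export
read_gcc_table <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  gcol <- if ("gcc_90" %in% names(df)) "gcc_90" else "gcc"
  if (!gcol %in% names(df)) stop("gcc table needs a gcc or gcc_90 column")
  if ("date" %in% names(df)) {
    dt <- as.Date(df$date)
    df$year <- as.integer(format(dt, "%Y"))
    df$doy <- as.integer(format(dt, "%j"))
  }
  if (!all(c("doy", "year") %in% names(df)))
    stop("gcc table needs date, or doy and year, columns")
  if (!"snow_flag" %in% names(df)) df$snow_flag <- FALSE
  out <- list()
  for (key in unique(paste(df$enclosure, df$roi, df$year, sep = "."))) {
    p <- strsplit(key, ".", fixed = TRUE)[[1]]
    d <- df[df$enclosure == p[1] & df$roi == p[2] & df$year == as.integer(p[3]), ]
    d <- d[order(d$doy), ]
    out[[key]] <- gcc_series(d$doy, d[[gcol]], as.logical(d$snow_flag),
                             enclosure = p[1], roi = p[2])
  }
  out
}
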