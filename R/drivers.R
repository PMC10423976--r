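#' @title Daily driver series for one enclosure-year
#' @description
#' A `driver_series` holds the aligned daily environmental drivers for one
#' enclosure and one focal year over an extended window running from 1
#' September of the previous year (day-of-year index -121; 31 December of the
#' previous year is day 0) through 31 December of the focal year. The
#' extended window exists so that chilling-accumulation models may start in
#' the previous autumn (negative `t0`).
#'
#' Fields: `enclosure` (id), `year` (focal calendar year), `doy` (integer
#' axis, strictly increasing, no gaps), `t_air` (2 m daily mean, degC),
#' `t_soil` (matrix, one column per measured depth 0, 5, 10, 20, 30, 40, 50,
#' 100, 200 cm), `wtd` (water table depth, cm relative to mean hollow height,
#' negative below), `co2` (ppm daily mean), `daylength` (h, from latitude),
#' `vpd` (kPa, optional, NULL when humidity was not supplied), `latitude`.
#' @name driver_series
NULL

.soil_depths <- c(0, 5, 10, 20, 30, 40, 50, 100, 200)

.default_schema <- function() {
  list(
    enclosure = "enclosure", date = "date", tair_c = "tair_c",
    tsoil = paste0("tsoil_", .soil_depths, "cm"),
    wtd_cm = "wtd_cm", co2_ppm = "co2_ppm", rh_pct = "rh_pct"
  )
}

new_driver_series <- function(enclosure, year, doy, t_air, t_soil, wtd, co2,
                              daylength, vpd = NULL, latitude = NA_real_) {
  n <- length(doy)
  stopifnot(all(diff(doy) == 1L), length(t_air) == n, nrow(t_soil) == n,
            length(wtd) == n, length(co2) == n, length(daylength) == n)
  if (!is.null(vpd)) stopifnot(length(vpd) == n)
  structure(list(enclosure = as.character(enclosure), year = as.integer(year),
                 doy = as.integer(doy), t_air = as.numeric(t_air),
                 t_soil = t_soil, wtd = as.numeric(wtd), co2 = as.numeric(co2),
                 daylength = as.numeric(daylength), vpd = vpd,
                 latitude = latitude),
            class = "driver_series")
}

#' @export
print.driver_series <- function(x, ...) {
  cat(sprintf("<driver_series> enclosure %s, focal year %d, %d days (doy %d..%d)\n",
              x$enclosure, x$year, length(x$doy), min(x$doy), max(x$doy)))
  cat(sprintf("  t_air mean %.2f degC; co2 mean %.0f ppm; vpd %s\n",
              mean(x$t_air), mean(x$co2),
              if (is.null(x$vpd)) "absent" else "present"))
  invisible(x)
}

# interpolate interior NA runs of length <= max_gap; longer runs are an
# error. A fully absent driver (all NA) is passed through untouched so it
# can be flagged absent downstream rather than zero-filled.
.fill_gaps <- function(x, dates, what, enclosure, max_gap = 3L) {
  if (!anyNA(x)) return(x)
  if (all(is.na(x))) return(x)
  r <- rle(is.na(x))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  bad <- which(r$values & r$lengths > max_gap)
  if (length(bad)) {
    i <- bad[1]
    stop(sprintf("gap of %d days in %s for enclosure %s (%s to %s); at most %d consecutive missing days are interpolated",
                 r$lengths[i], what, enclosure, dates[starts[i]], dates[ends[i]], max_gap))
  }
  idx <- seq_along(x)
  ok <- !is.na(x)
  if (sum(ok) < 2) stop(sprintf("not enough data in %s for enclosure %s", what, enclosure))
  approx(idx[ok], x[ok], xout = idx, rule = 2)$y
}

# signed doy index: focal-year dates get their ordinary day of year, previous
# year dates count back from 0 at 31 December of the previous year.
.signed_doy <- function(dates, focal_year) {
  yr <- as.integer(format(dates, "%Y"))
  yd <- as.integer(format(dates, "%j"))
  prev_len <- as.integer(format(as.Date(sprintf("%d-12-31", focal_year - 1L)), "%j"))
  ifelse(yr == focal_year, yd, yd - prev_len)
}

#' Read a daily driver table into driver series
#'
#' Reads a delimited file with one row per enclosure-day and builds one
#' [driver_series] per (enclosure, focal year). A year qualifies as focal
#' when both the complete focal calendar year and the previous 1 September -
#' 31 December window are present. Missing days inside the window are
#' linearly interpolated up to 3 consecutive days; longer gaps raise an
#' error naming the date range. Missing optional drivers (humidity) leave
#' `vpd` absent rather than zero-filled.
#'
#' @param path CSV/TSV file with a header. Default columns: `enclosure`,
#'   `date` (ISO-8601), `tair_c`, `tsoil_0cm` ... `tsoil_200cm`, `wtd_cm`,
#'   `co2_ppm` and optionally `rh_pct`.
#' @param schema optional column mapping: either a YAML file path or a named
#'   list with entries `enclosure`, `date`, `tair_c`, `tsoil` (character
#'   vector of nine depth columns), `wtd_cm`, `co2_ppm`, `rh_pct`.
#' @param latitude site latitude (degrees) for daylength, default 47.5.
#' @param sep field separator; `","` default, use `"\t"` for TSV.
#' @return a list of [driver_series] objects.
#' @export
read_driver_table <- function(path, schema = NULL, latitude = 47.5, sep = ",") {
  if (!file.exists(path)) stop("file not found: ", path)
  sc <- .default_schema()
  if (is.character(schema) && length(schema) == 1) schema <- yaml::read_yaml(schema)
  if (!is.null(schema)) sc[names(schema)] <- schema
  df <- read.csv(path, sep = sep, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c(sc$enclosure, sc$date, sc$tair_c)
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("driver table schema error: missing column(s) ",
                         paste(miss, collapse = ", "))
  opt <- function(col) if (col %in% names(df)) df[[col]] else NA_real_
  out <- data.frame(enclosure = as.character(df[[sc$enclosure]]),
                    date = as.Date(df[[sc$date]]), tair_c = df[[sc$tair_c]],
                    wtd_cm = opt(sc$wtd_cm), co2_ppm = opt(sc$co2_ppm),
                    stringsAsFactors = FALSE)
  for (i in seq_along(.soil_depths))
    out[[paste0("tsoil_", .soil_depths[i], "cm")]] <- opt(sc$tsoil[i])
  if (!is.null(sc$rh_pct) && sc$rh_pct %in% names(df)) out$rh_pct <- df[[sc$rh_pct]]
  build_driver_series(out, latitude = latitude)
}

#' Build driver series from a canonical daily table
#'
#' Lower-level constructor used by [read_driver_table()] and the synthetic
#' generator. `table` must hold canonical columns (see [read_driver_table()]),
#' with `date` of class `Date`.
#'
#' @param table data frame of daily rows, one per enclosure-day.
#' @param latitude degrees north.
#' @return list of [driver_series].
#' @export
build_driver_series <- function(table, latitude = 47.5) {
  series <- list()
  soil_cols <- paste0("tsoil_", .soil_depths, "cm")
  for (enc in unique(table$enclosure)) {
    d <- table[table$enclosure == enc, , drop = FALSE]
    d <- d[order(d$date), , drop = FALSE]
    dup <- d$date[duplicated(d$date)]
    if (length(dup))
      stop(sprintf("duplicate date %s for enclosure %s", dup[1], enc))
    years <- sort(unique(as.integer(format(d$date, "%Y"))))
    for (yr in years) {
      w0 <- as.Date(sprintf("%d-09-01", yr - 1L))
      w1 <- as.Date(sprintf("%d-12-31", yr))
      if (!any(d$date <= w0) || !any(d$date >= w1)) next
      days <- seq(w0, w1, by = "day")
      m <- match(days, d$date)
      get <- function(col) .fill_gaps(d[[col]][m], days, col, enc)
      t_soil <- vapply(soil_cols, get, numeric(length(days)))
      colnames(t_soil) <- soil_cols
      doy <- .signed_doy(days, yr)
      vpd <- NULL
      if ("rh_pct" %in% names(d) && !all(is.na(d$rh_pct[m]))) {
        rh <- .fill_gaps(d$rh_pct[m], days, "rh_pct", enc)
        vpd <- compute_vpd(get("tair_c"), rh)
      }
      series[[length(series) + 1L]] <- new_driver_series(
        enclosure = enc, year = yr, doy = doy, t_air = get("tair_c"),
        t_soil = t_soil, wtd = get("wtd_cm"), co2 = get("co2_ppm"),
        daylength = compute_daylength(latitude, ((doy - 1) %% 366) + 1),
        vpd = vpd, latitude = latitude)
    }
  }
  series
}

#' Write a canonical daily driver table
#'
#' Writes the canonical daily table (as produced by [simulate_drivers()]) to
#' CSV at full double precision so that a write/read cycle is lossless.
#'
#' @param table canonical daily data frame.
#' @param path output file.
#' @export
write_driver_table <- function(table, path) {
  out <- table
  for (nm in names(out)) {
    if (is.numeric(out[[nm]]) && !is.integer(out[[nm]]))
      out[[nm]] <- sprintf("%.17g", out[[nm]])
  }
  out$date <- as.character(table$date)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Enclosure metadata table
#'
#' Validates and normalizes a metadata table describing each enclosure: its
#' nominal warming target (one of 0, 2.25, 4.5, 6.75, 9 degC), CO2 treatment
#' (`ambient`/`elevated`), the measured mean annual 2 m air-temperature
#' differential relative to the unheated controls, and coordinates.
#'
#' @param enclosure character ids.
#' @param target_warming nominal warming offsets (degC).
#' @param co2_treatment `"ambient"` or `"elevated"`.
#' @param measured_warming measured differentials (degC); defaults to the
#'   nominal target.
#' @param latitude,longitude degrees.
#' @return data frame of class `enclosure_metadata`.
#' @export
enclosure_metadata <- function(enclosure, target_warming, co2_treatment,
                               measured_warming = target_warming,
                               latitude = 47.5, longitude = -93.45) {
  lv <- c(0, 2.25, 4.5, 6.75, 9)
  if (!all(target_warming %in% lv))
    stop("target_warming must be one of ", paste(lv, collapse = ", "))
  if (!all(co2_treatment %in% c("ambient", "elevated")))
    stop("co2_treatment must be 'ambient' or 'elevated'")
  if (any(latitude < -90 | latitude > 90)) stop("latitude out of range")
  out <- data.frame(enclosure = as.character(enclosure),
                    target_warming = target_warming,
                    co2_treatment = co2_treatment,
                    measured_warming = measured_warming,
                    latitude = latitude, longitude = longitude,
                    stringsAsFactors = FALSE)
  class(out) <- c("enclosure_metadata", "data.frame")
  out
}

#' Read and write transition-date tables
#'
#' Transition tables hold one row per (enclosure, year, pft, season):
#' columns `enclosure`, `year`, `pft` (DN/EN/SH), `season`
#' (spring/autumn), `doy`, `ci_lower`, `ci_upper` (90% interval).
#'
#' @param path CSV file.
#' @return data frame of observations.
#' @export
read_transition_table <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("enclosure", "year", "pft", "season", "doy")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("transition table missing column(s): ",
                         paste(miss, collapse = ", "))
  if (!all(df$pft %in% c("DN", "EN", "SH"))) stop("pft must be DN, EN or SH")
  if (!all(df$season %in% c("spring", "autumn")))
    stop("season must be spring or autumn")
  if (all(c("ci_lower", "ci_upper") %in% names(df))) {
    ok <- is.na(df$ci_lower) | (df$ci_lower <= df$doy & df$doy <= df$ci_upper)
    if (!all(ok)) stop("ci_lower <= doy <= ci_upper violated at row ",
                       which(!ok)[1])
  }
  df$enclosure <- as.character(df$enclosure)
  df
}

#' @rdname read_transition_table
#' @param transitions data frame of observations.
#' @export
write_transition_table <- function(transitions, path) {
  write.csv(transitions, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
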