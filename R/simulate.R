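# Synthetic enclosure-experiment generator. Emulates the statistical
# structure the analysis assumes -- 10 open-top enclosures at five nominal
# warming levels (0, +2.25, +4.5, +6.75, +9 degC, two enclosures each), half
# receiving +500 ppm CO2 during the growing season, at a boreal bog site
# (latitude 47.5 N, mean annual temperature 3.4 degC) -- so every stage of
# the pipeline can be exercised and tested without external data.

#' Default sensitivity coefficient sets for the synthetic experiment
#'
#' The generating fixed effects used by [simulate_transitions_lme()]:
#' transition DOY intercept, temperature slope (days per degC of measured
#' warming), CO2 treatment effect (days) and temperature-by-CO2 interaction
#' (days per degC) for each plant functional type (DN deciduous needleleaf,
#' EN evergreen needleleaf, SH shrub layer) and season. The spring sets carry
#' temperature only; the autumn DN set carries temperature, CO2 and their
#' interaction; autumn EN temperature and CO2; autumn SH temperature only --
#' the final-model structure estimated from the enclosure experiment this
#' generator emulates. `slope_se` is the reported standard error of the
#' temperature slope and `resid_sd` the residual SD implied by it under the
#' 10-enclosure x 5-year design (see the methods vignette).
#'
#' @return data frame with one row per (pft, season) coefficient set.
#' @export
sensitivity_defaults <- function() {
  data.frame(
    pft = c("DN", "EN", "SH", "DN", "EN", "SH"),
    season = rep(c("spring", "autumn"), each = 3),
    intercept = c(118.09, 92.69, 139.39, 286.56, 307.85, 288.38),
    temp = c(-1.59, -1.94, -1.0, 1.86, 1.77, 3.06),
    slope_se = c(0.19, 0.29, 0.16, 0.29, 0.26, 0.38),
    co2 = c(0, 0, 0, -16.94, -4.22, 0),
    co2_se = c(NA, NA, NA, 3.02, 1.63, NA),
    interaction = c(0, 0, 0, 1.38, 0, 0),
    interaction_se = c(NA, NA, NA, 0.50, NA, NA),
    resid_sd = c(4.3, 6.5, 3.6, 6.5, 5.9, 8.6),
    stringsAsFactors = FALSE)
}

#' Simulate daily enclosure drivers
#'
#' Generates the canonical daily driver table and [driver_series] for a
#' synthetic warming-by-CO2 enclosure experiment. Air temperature is a
#' seasonal sinusoid around the site mean plus AR(1) weather noise (shared
#' across enclosures, so the enclosure temperature differential equals the
#' warming offset by construction) plus the enclosure offset. Soil
#' temperature at each depth is the enclosure air signal passed through a
#' first-order low-pass filter whose smoothing weight decreases with depth,
#' yielding the damping and lag of a conductive profile. CO2 is constant at
#' ambient and stepped up by `co2_step` during days `co2_window` in elevated
#' enclosures. Water table follows a seasonal drawdown curve (high after
#' snowmelt, -20 to -30 cm in midsummer) plus noise. Relative humidity is
#' seasonal with noise, from which VPD is derived. One spin-up calendar year
#' precedes the first focal year so every focal year has its
#' previous-autumn window.
#'
#' @param n_years number of focal years (default 5).
#' @param start_year first focal calendar year.
#' @param latitude degrees north (default 47.5).
#' @param mat site mean annual temperature, degC (default 3.4).
#' @param amplitude seasonal half-amplitude of daily mean temperature, degC.
#' @param ar1,innov_sd AR(1) coefficient (in \[0,1)) and innovation SD (degC)
#'   of the daily weather noise.
#' @param offsets per-enclosure warming offsets, degC.
#' @param co2_elevated logical per enclosure.
#' @param co2_ambient,co2_step ambient level and growing-season elevation,
#'   ppm.
#' @param co2_window days of year of the elevated-CO2 fumigation period.
#' @param soil_alpha low-pass smoothing weights for the nine soil depths
#'   (0..200 cm), decreasing with depth.
#' @param seed master seed; output is bit-reproducible given it.
#' @return list with `drivers` (list of [driver_series]), `metadata`
#'   ([enclosure_metadata()] with the measured warming differential computed
#'   from the generated series), `table` (canonical daily data frame) and
#'   the call parameters in `config`.
#' @export
simulate_drivers <- function(n_years = 5, start_year = 2016, latitude = 47.5,
                             mat = 3.4, amplitude = 16, ar1 = 0.7,
                             innov_sd = 3,
                             offsets = rep(c(0, 2.25, 4.5, 6.75, 9), each = 2),
                             co2_elevated = rep(c(FALSE, TRUE), 5),
                             co2_ambient = 400, co2_step = 500,
                             co2_window = c(120, 280),
                             soil_alpha = c(0.55, 0.40, 0.30, 0.20, 0.15,
                                            0.12, 0.10, 0.05, 0.02),
                             seed = 1) {
  stopifnot(ar1 >= 0, ar1 < 1, innov_sd >= 0, all(offsets >= 0),
            length(co2_elevated) == length(offsets),
            length(soil_alpha) == length(.soil_depths))
  set.seed(seed)
  n_enc <- length(offsets)
  enc <- sprintf("E%02d", seq_len(n_enc))
  dates <- seq(as.Date(sprintf("%d-01-01", start_year - 1)),
               as.Date(sprintf("%d-12-31", start_year + n_years - 1)), "day")
  nd <- length(dates)
  yd <- as.integer(format(dates, "%j"))
  seasonal <- mat - amplitude * cos(2 * pi * (yd - 15) / 365.25)
  e <- numeric(nd)
  innov <- rnorm(nd, 0, innov_sd)
  e[1] <- innov[1]
  for (t in 2:nd) e[t] <- ar1 * e[t - 1] + innov[t]
  base_air <- seasonal + e
  wtd_season <- 8 - 30 * exp(-0.5 * ((yd - 200) / 55)^2)
  rh_season <- 78 + 8 * cos(2 * pi * (yd - 15) / 365.25)
  rows <- vector("list", n_enc)
  for (i in seq_len(n_enc)) {
    tair <- base_air + offsets[i]
    soil <- matrix(0, nd, length(soil_alpha))
    for (j in seq_along(soil_alpha)) {
      a <- soil_alpha[j]
      s <- numeric(nd)
      s[1] <- mat + offsets[i]
      for (t in 2:nd) s[t] <- s[t - 1] + a * (tair[t] - s[t - 1])
      soil[, j] <- s
    }
    wtd <- wtd_season + rnorm(nd, 0, 1.5)
    rh <- pmin(pmax(rh_season + rnorm(nd, 0, 5), 25), 100)
    co2 <- rep(co2_ambient, nd)
    if (co2_elevated[i])
      co2[yd >= co2_window[1] & yd <= co2_window[2]] <- co2_ambient + co2_step
    r <- data.frame(enclosure = enc[i], date = dates, tair_c = tair,
                    stringsAsFactors = FALSE)
    for (j in seq_along(.soil_depths))
      r[[paste0("tsoil_", .soil_depths[j], "cm")]] <- soil[, j]
    r$wtd_cm <- wtd; r$co2_ppm <- co2; r$rh_pct <- rh
    rows[[i]] <- r
  }
  table <- do.call(rbind, rows)
  focal <- as.integer(format(dates, "%Y")) >= start_year
  ctrl <- which(offsets == 0)
  mean_air <- vapply(rows, function(r) mean(r$tair_c[focal]), numeric(1))
  measured <- mean_air - mean(mean_air[ctrl])
  metadata <- enclosure_metadata(
    enclosure = enc, target_warming = offsets,
    co2_treatment = ifelse(co2_elevated, "elevated", "ambient"),
    measured_warming = measured, latitude = latitude)
  list(drivers = build_driver_series(table, latitude = latitude),
       metadata = metadata, table = table,
       config = list(n_years = n_years, start_year = start_year,
                     latitude = latitude, mat = mat, amplitude = amplitude,
                     ar1 = ar1, innov_sd = innov_sd, offsets = offsets,
                     co2_elevated = co2_elevated, co2_ambient = co2_ambient,
                     co2_step = co2_step, co2_window = co2_window,
                     seed = seed))
}

#' Simulate transition dates from a linear mixed-effects structure
#'
#' Draws transition DOYs as
#' `intercept + temp * dT + co2 * flag + interaction * dT * flag +
#' year_effect + residual`, with a year effect shared across enclosures
#' within a year, rounded to integer days.
#'
#' @param metadata an [enclosure_metadata()] table (`measured_warming`
#'   supplies dT, `co2_treatment` the flag).
#' @param years focal calendar years.
#' @param pft,season labels for the generated observations.
#' @param coefficients one row of [sensitivity_defaults()] (or a list with
#'   `intercept`, `temp`, `co2`, `interaction`, `resid_sd`); defaults to the
#'   packaged set for (`pft`, `season`).
#' @param year_sd SD of the shared year effect, days (default 3).
#' @param seed integer seed.
#' @return transition data frame (`enclosure`, `year`, `pft`, `season`,
#'   `doy`, `ci_lower`, `ci_upper`).
#' @export
simulate_transitions_lme <- function(metadata, years, pft, season,
                                     coefficients = NULL, year_sd = 3,
                                     seed = 1) {
  if (is.null(coefficients)) {
    sd0 <- sensitivity_defaults()
    coefficients <- sd0[sd0$pft == pft & sd0$season == season, ]
    if (!nrow(coefficients)) stop("no default coefficient set for ", pft,
                                  " ", season)
  }
  co <- as.list(coefficients)
  set.seed(seed)
  yeff <- setNames(rnorm(length(years), 0, year_sd), years)
  g <- expand.grid(enclosure = metadata$enclosure, year = years,
                   stringsAsFactors = FALSE)
  m <- match(g$enclosure, metadata$enclosure)
  dT <- metadata$measured_warming[m]
  flag <- as.numeric(metadata$co2_treatment[m] == "elevated")
  mu <- co$intercept + co$temp * dT + co$co2 * flag +
    co$interaction * dT * flag + yeff[as.character(g$year)]
  doy <- round(mu + rnorm(nrow(g), 0, co$resid_sd))
  data.frame(enclosure = g$enclosure, year = g$year, pft = pft,
             season = season, doy = as.integer(doy),
             ci_lower = as.integer(doy) - 2L, ci_upper = as.integer(doy) + 2L,
             stringsAsFactors = FALSE)
}

#' Simulate transition dates from a process model
#'
#' Forward-runs a named phenology model on each enclosure-year's drivers and
#' adds Gaussian observation noise (rounded to integer days). Enclosure-years
#' for which the model returns the no-transition sentinel are dropped with a
#' message reporting the count.
#'
#' @param drivers list of [driver_series].
#' @param model,params model abbreviation and named truth parameters.
#' @param pft,season labels for the generated observations.
#' @param noise_sd observation noise SD, days (0 for exact model output).
#' @param temp_channel temperature channel the truth model uses.
#' @param seed integer seed.
#' @return transition data frame as in [simulate_transitions_lme()].
#' @export
simulate_transitions_process <- function(drivers, model, params, pft = "DN",
                                         season = NULL, noise_sd = 0,
                                         temp_channel = "air", seed = 1) {
  spec <- pheno_model(model)
  if (is.null(season)) season <- spec$season
  pred <- predict_phenology(spec, params, drivers, temp_channel)
  drop <- is.na(pred)
  if (any(drop))
    message(sum(drop), " enclosure-year(s) produced no transition and were dropped")
  keep <- which(!drop)
  set.seed(seed)
  doy <- round(pred[keep] + rnorm(length(keep), 0, noise_sd))
  data.frame(
    enclosure = vapply(drivers[keep], `[[`, character(1), "enclosure"),
    year = vapply(drivers[keep], `[[`, integer(1), "year"),
    pft = pft, season = season, doy = as.integer(doy),
    ci_lower = as.integer(doy) - 2L, ci_upper = as.integer(doy) + 2L,
    stringsAsFactors = FALSE)
}

#' Simulate a daily greenness series with known transition dates
#'
#' Builds a double-logistic greenness curve whose 25%-amplitude crossings
#' fall exactly at the supplied spring and autumn DOYs (the logistic
#' midpoints are placed at `spring + log(3)/r_spring` and
#' `autumn - log(3)/r_autumn`), adds observation noise, and depresses and
#' flags the listed snow days.
#'
#' @param spring,autumn transition days of year; `autumn > spring` required.
#' @param base,amplitude greenness baseline and seasonal amplitude.
#' @param r_spring,r_autumn logistic steepness of green-up and green-down.
#' @param noise_sd additive observation noise SD.
#' @param snow_days integer days to contaminate and flag.
#' @param snow_dip downward shift applied on snow days.
#' @param seed integer seed.
#' @param enclosure,roi identifiers attached to the series.
#' @return a [gcc_series()] over days 1..365.
#' @export
simulate_gcc <- function(spring, autumn, base = 0.33, amplitude = 0.10,
                         r_spring = 0.30, r_autumn = 0.15, noise_sd = 0,
                         snow_days = integer(), snow_dip = 0.05, seed = 1,
                         enclosure = NA_character_, roi = NA_character_) {
  if (autumn <= spring) stop("autumn transition must fall after spring")
  d <- 1:365
  m_s <- spring + log(3) / r_spring
  m_a <- autumn - log(3) / r_autumn
  g <- base + amplitude * plogis(r_spring * (d - m_s)) *
    plogis(-r_autumn * (d - m_a))
  set.seed(seed)
  g <- g + rnorm(365, 0, noise_sd)
  flag <- d %in% snow_days
  g[flag] <- g[flag] - snow_dip
  g <- pmin(pmax(g, 0.01), 0.99)
  gcc_series(d, g, flag, enclosure = enclosure, roi = roi)
}
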