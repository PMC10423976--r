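# Model evaluation environment and the 29-model registry.
#
# All models are evaluated in matrix form: one column per enclosure-year
# observation, one row per day of the extended driver window (doy -121..365,
# day 0 = 31 Dec of the previous year). Accumulation and threshold crossing
# run through the compiled kernels (col_cumsum / first_crossing / first_ge),
# which keeps a full simulated-annealing fit fast in pure R otherwise.

#' Build a model evaluation environment from driver series
#'
#' Aligns a collection of [driver_series] on the common day axis -121..365
#' and assembles the driver matrices the models consume. Day 366 of leap
#' focal years falls outside the common axis and is dropped.
#'
#' @param drivers a [driver_series] or list of them.
#' @param temp_channel temperature driver: `"air"` or a soil depth in cm
#'   (one of 0, 5, 10, 20, 30, 40, 50, 100, 200, as number or string).
#' @return an environment-like list with the day axis, temperature /
#'   daylength / water-table / VPD matrices (days x observations), the
#'   growing-season mean CO2 per observation and column labels
#'   `"<enclosure>.<year>"`.
#' @export
build_model_env <- function(drivers, temp_channel = "air") {
  if (inherits(drivers, "driver_series")) drivers <- list(drivers)
  doy <- -121:365
  nd <- length(doy)
  ch <- as.character(temp_channel)
  pick_temp <- function(ds) {
    if (ch == "air") ds$t_air
    else {
      col <- paste0("tsoil_", ch, "cm")
      if (!col %in% colnames(ds$t_soil))
        stop("driver error: temperature channel '", ch, "' not available")
      ds$t_soil[, col]
    }
  }
  grab <- function(f) vapply(drivers, function(ds) f(ds)[match(doy, ds$doy)],
                             numeric(nd))
  temp <- grab(pick_temp)
  if (anyNA(temp)) stop("driver series do not cover the full -121..365 window")
  dayl <- grab(function(ds) ds$daylength)
  wtd <- grab(function(ds) ds$wtd)
  if (anyNA(wtd)) wtd <- NULL # water-table channel absent
  co2 <- grab(function(ds) ds$co2)
  if (anyNA(co2)) co2[] <- 400 # ambient fallback when CO2 was not recorded
  vpd <- if (all(vapply(drivers, function(d) !is.null(d$vpd), logical(1))))
    grab(function(ds) ds$vpd) else NULL
  gs <- doy >= 120 & doy <= 280
  list(doy = doy, doy0 = doy[1], n_days = nd, n = length(drivers),
       cache = new.env(parent = emptyenv()),
       temp = temp, dayl = dayl, wtd = wtd, vpd = vpd,
       co2_gs = colMeans(co2[gs, , drop = FALSE]),
       labels = vapply(drivers, function(d) paste(d$enclosure, d$year, sep = "."),
                       character(1)))
}

# accumulation starts the day AFTER the start-date parameter, so with a
# constant unit rate and requirement F the crossing lands on day t0 + F
.idx <- function(env, t0) {
  i <- as.integer(ceiling(t0)) + 1L - env$doy0 + 1L
  min(max(i, 1L), env$n_days)
}

.doy_at <- function(env, ix) ifelse(ix == 0L, NA_real_, env$doy[pmax(ix, 1L)])

# spring transitions are only valid within DOY 1..243 (1 Jan .. end of
# August); a crossing outside that window is ecologically meaningless for
# budburst and is returned as the no-transition sentinel
.spring_doy <- function(env, ix) {
  d <- .doy_at(env, ix)
  d[!is.na(d) & (d < 1 | d > 243)] <- NA_real_
  d
}

.all_na <- function(env) rep(NA_real_, env$n)

.zero_before <- function(m, i) {
  if (i > 1L) m[seq_len(i - 1L), ] <- 0
  m
}

# ---- spring families ------------------------------------------------------

# memoise the expensive rate matrices on the evaluation environment: the
# optimizer mostly moves one parameter at a time, so consecutive cost
# evaluations reuse most of these
.memo <- function(env, slot, key, build) {
  ch <- env$cache
  if (is.null(ch)) return(build())
  kslot <- paste0(slot, "_key")
  if (!identical(ch[[kslot]], key)) {
    ch[[slot]] <- build()
    ch[[kslot]] <- key
  }
  ch[[slot]]
}

.spring_forcing <- function(env, p, form, photoperiod) {
  r <- if (form == "linear")
    .memo(env, "flin", p[["T_base"]],
          function() forcing_rate_linear(env$temp, p[["T_base"]]))
  else
    .memo(env, "fsig", c(p[["b_f"]], p[["c_f"]]),
          function() forcing_rate_sigmoid(env$temp, p[["b_f"]], p[["c_f"]]))
  if (photoperiod == "ptt") r <- r * (env$dayl / 24)
  if (photoperiod == "m1")
    r <- r * .memo(env, "m1", p[["k"]],
                   function() (env$dayl / 10)^p[["k"]])
  r
}

.predict_tt_family <- function(env, p, form, photoperiod) {
  r <- .spring_forcing(env, p, form, photoperiod)
  i0 <- .idx(env, p[["t0"]])
  ix <- first_crossing(r, rep(i0, env$n), rep(p[["F_star"]], env$n))
  .spring_doy(env, ix)
}

.chill_matrix <- function(env, p, shape) {
  if (shape == "triangular") {
    if (!(p[["T_min"]] < p[["T_opt"]] && p[["T_opt"]] < p[["T_max"]]))
      return(NULL) # parameter-domain violation -> sentinel penalty upstream
    .memo(env, "ctri", c(p[["T_min"]], p[["T_opt"]], p[["T_max"]]),
          function() chilling_rate_triangular(env$temp, p[["T_min"]],
                                              p[["T_opt"]], p[["T_max"]]))
  } else {
    .memo(env, "cbell", c(p[["a_c"]], p[["b_c"]], p[["c_c"]]),
          function() chilling_rate_bell(env$temp, p[["a_c"]], p[["b_c"]],
                                        p[["c_c"]]))
  }
}

.predict_sequential <- function(env, p, shape, photoperiod) {
  cr <- .chill_matrix(env, p, shape)
  if (is.null(cr)) return(.all_na(env))
  ic <- .idx(env, p[["t0_chill"]])
  rel <- first_crossing(cr, rep(ic, env$n), rep(p[["C_star"]], env$n))
  i0 <- .idx(env, p[["t0"]])
  # forcing starts the day the chilling requirement is met (inclusive) and
  # not before t0; forcing accumulated earlier is discarded
  start <- ifelse(rel == 0L, 0L, pmax(rel, i0))
  fr <- .spring_forcing(env, p, "linear", photoperiod)
  ix <- first_crossing(fr, as.integer(start), rep(p[["F_star"]], env$n))
  .spring_doy(env, ix)
}

.predict_parallel <- function(env, p, shape, photoperiod) {
  cr <- .chill_matrix(env, p, shape)
  if (is.null(cr)) return(.all_na(env))
  ic <- .idx(env, p[["t0_chill"]])
  C <- col_cumsum(.zero_before(cr, ic))
  K <- if (p[["C_star"]] <= 0) 1
       else p[["K_min"]] + (1 - p[["K_min"]]) * pmin(1, C / p[["C_star"]])
  fr <- .spring_forcing(env, p, "linear", photoperiod) * K
  i0 <- .idx(env, p[["t0"]])
  ix <- first_crossing(fr, rep(i0, env$n), rep(p[["F_star"]], env$n))
  .spring_doy(env, ix)
}

.predict_um1 <- function(env, p) {
  ic <- .idx(env, p[["t0_chill"]])
  C <- col_cumsum(.zero_before(chilling_rate_bell(env$temp, p[["a_c"]],
                                                  p[["b_c"]], p[["c_c"]]), ic))
  fr <- forcing_rate_sigmoid(env$temp, p[["b_f"]], p[["c_f"]]) *
    (env$dayl / 10)^p[["k"]]
  S <- col_cumsum(.zero_before(fr, ic))
  thr <- p[["w"]] * exp(-p[["z"]] * C)
  ix <- first_ge(S, thr, rep(ic, env$n))
  .spring_doy(env, ix)
}

.predict_at <- function(env, p) {
  i0 <- .idx(env, p[["t0"]])
  chill_day <- (env$temp < p[["T_base"]]) * 1
  Cd <- col_cumsum(.zero_before(chill_day, i0))
  G <- col_cumsum(.zero_before(forcing_rate_linear(env$temp, p[["T_base"]]), i0))
  thr <- p[["a"]] + p[["b"]] * exp(p[["c"]] * Cd)
  ix <- first_ge(G, thr, rep(i0, env$n))
  .spring_doy(env, ix)
}

.predict_lin <- function(env, p, window = c(1, 120)) {
  sel <- env$doy >= window[1] & env$doy <= window[2]
  p[["a"]] + p[["b"]] * colMeans(env$temp[sel, , drop = FALSE])
}

.gsi_index <- function(env, p) {
  if (is.null(env$vpd))
    stop("driver error: VPD channel required for growing-season-index models")
  if (!(p[["T_lo"]] < p[["T_hi"]] && p[["V_lo"]] < p[["V_hi"]] &&
        p[["L_lo"]] < p[["L_hi"]])) return(NULL)
  .ramp(env$temp, p[["T_lo"]], p[["T_hi"]]) *
    (1 - .ramp(env$vpd, p[["V_lo"]], p[["V_hi"]])) *
    .ramp(env$dayl, p[["L_lo"]], p[["L_hi"]])^p[["k"]]
}

.predict_sgsi <- function(env, p, smooth_window = 21L) {
  ind <- .gsi_index(env, p)
  if (is.null(ind)) return(.all_na(env))
  CS <- col_cumsum(ind)
  w <- smooth_window
  ma <- CS
  ma[seq_len(w), ] <- CS[seq_len(w), ] / seq_len(w)
  if (env$n_days > w)
    ma[(w + 1):env$n_days, ] <-
      (CS[(w + 1):env$n_days, , drop = FALSE] -
       CS[1:(env$n_days - w), , drop = FALSE]) / w
  i0 <- .idx(env, p[["t0"]])
  thr <- matrix(p[["thresh"]], env$n_days, env$n)
  ix <- first_ge(ma, thr, rep(i0, env$n))
  .spring_doy(env, ix)
}

.predict_agsi <- function(env, p) {
  ind <- .gsi_index(env, p)
  if (is.null(ind)) return(.all_na(env))
  i0 <- .idx(env, p[["t0"]])
  ix <- first_crossing(ind, rep(i0, env$n), rep(p[["F_star"]], env$n))
  .spring_doy(env, ix)
}

# ---- autumn families ------------------------------------------------------

.autumn_threshold <- function(env, p, co2) {
  if (co2) co2_threshold_offset(p[["F_star"]], p[["c_co2"]], env$co2_gs)
  else rep(p[["F_star"]], env$n)
}

.predict_cdd <- function(env, p, form, weight = "none", co2 = FALSE,
                         photoperiod_weight = c("deficit", "fraction")) {
  photoperiod_weight <- match.arg(photoperiod_weight)
  r <- if (form == "linear") cold_rate(env$temp, "linear", T_base = p[["T_base"]])
       else cold_rate(env$temp, "sigmoid", b_s = p[["b_s"]], c_s = p[["c_s"]])
  if (weight == "photoperiod")
    r <- r * (if (photoperiod_weight == "deficit") 1 - env$dayl / 24
              else env$dayl / 24)
  if (weight == "water") {
    if (is.null(env$wtd))
      stop("driver error: water-table channel required")
    r <- r * pmax(1 + p[["m"]] * env$wtd, 0)
  }
  i0 <- .idx(env, p[["t0"]])
  ix <- first_crossing(r, rep(i0, env$n), .autumn_threshold(env, p, co2))
  .doy_at(env, ix)
}

.predict_ppm <- function(env, p, co2 = FALSE) {
  if (is.null(env$wtd))
    stop("driver error: water-table channel required")
  r <- pmax(p[["L_crit"]] - env$dayl, 0) * pmax(1 + p[["m"]] * env$wtd, 0)
  focal <- which(env$doy >= 1)
  i_sol <- focal[which.max(env$dayl[focal, 1])] # summer solstice start
  ix <- first_crossing(r, rep(i_sol, env$n), .autumn_threshold(env, p, co2))
  .doy_at(env, ix)
}

# ---- registry -------------------------------------------------------------

.mk <- function(name, season, drivers, params, lower, upper, fn) {
  stopifnot(length(params) == length(lower), length(params) == length(upper))
  structure(list(name = name, season = season, drivers = drivers,
                 params = params,
                 lower = setNames(lower, params),
                 upper = setNames(upper, params), fn = fn),
            class = "pheno_model_spec")
}

#' @export
print.pheno_model_spec <- function(x, ...) {
  cat(sprintf("<pheno_model_spec> %s (%s; drivers %s; %d parameters)\n",
              x$name, x$season, x$drivers, length(x$params)))
  b <- rbind(lower = x$lower, upper = x$upper)
  print(b)
  invisible(x)
}

.registry <- local({
  # shared default bounds (uniform search ranges for the optimizer)
  b <- list(
    t0 = c(-60, 150), t0_chill = c(-121, 60), T_base = c(-5, 15),
    F_star = c(1, 500), b_f = c(0.05, 3), c_f = c(-5, 25), k = c(0, 4),
    T_min = c(-30, 0), T_opt = c(-15, 10), T_max = c(0, 20),
    C_star = c(1, 150), a_c = c(0.01, 2), b_c = c(-3, 3), c_c = c(-10, 15),
    K_min = c(0, 1), a_at = c(0, 1000), b_at = c(0, 5000), c_at = c(-2, 0),
    w = c(1, 500), z = c(0, 0.5), a_lin = c(0, 250), b_lin = c(-30, 30),
    T_lo = c(-10, 10), T_hi = c(10.5, 35), V_lo = c(0, 1.5), V_hi = c(1.6, 6),
    L_lo = c(0, 12), L_hi = c(12.5, 24), thresh = c(0.01, 0.99),
    F_gsi = c(1, 200),
    t0_aut = c(180, 300), T_base_aut = c(0, 30), F_aut = c(1, 1000),
    b_s = c(0.05, 3), c_s = c(0, 25), c_co2 = c(0, 0.2), m = c(-0.03, 0.03),
    L_crit = c(10, 24)
  )
  lo <- function(keys) vapply(keys, function(k) b[[k]][1], numeric(1))
  hi <- function(keys) vapply(keys, function(k) b[[k]][2], numeric(1))
  sp <- function(name, drv, params, keys, fn)
    .mk(name, "spring", drv, params, lo(keys), hi(keys), fn)
  au <- function(name, drv, params, keys, fn)
    .mk(name, "autumn", drv, params, lo(keys), hi(keys), fn)

  tri <- c("T_min", "T_opt", "T_max"); bel <- c("a_c", "b_c", "c_c")

  list(
    LIN  = sp("LIN", "F", c("a", "b"), c("a_lin", "b_lin"),
              function(p, env) .predict_lin(env, p)),
    TT   = sp("TT", "F", c("t0", "T_base", "F_star"),
              c("t0", "T_base", "F_star"),
              function(p, env) .predict_tt_family(env, p, "linear", "none")),
    TTs  = sp("TTs", "F", c("t0", "b_f", "c_f", "F_star"),
              c("t0", "b_f", "c_f", "F_star"),
              function(p, env) .predict_tt_family(env, p, "sigmoid", "none")),
    PTT  = sp("PTT", "PF", c("t0", "T_base", "F_star"),
              c("t0", "T_base", "F_star"),
              function(p, env) .predict_tt_family(env, p, "linear", "ptt")),
    PTTs = sp("PTTs", "PF", c("t0", "b_f", "c_f", "F_star"),
              c("t0", "b_f", "c_f", "F_star"),
              function(p, env) .predict_tt_family(env, p, "sigmoid", "ptt")),
    M1   = sp("M1", "PF", c("t0", "T_base", "k", "F_star"),
              c("t0", "T_base", "k", "F_star"),
              function(p, env) .predict_tt_family(env, p, "linear", "m1")),
    M1s  = sp("M1s", "PF", c("t0", "b_f", "c_f", "k", "F_star"),
              c("t0", "b_f", "c_f", "k", "F_star"),
              function(p, env) .predict_tt_family(env, p, "sigmoid", "m1")),
    AT   = sp("AT", "CF", c("t0", "T_base", "a", "b", "c"),
              c("t0", "T_base", "a_at", "b_at", "c_at"),
              function(p, env) .predict_at(env, p)),
    SQ   = sp("SQ", "CF",
              c("t0", "t0_chill", tri, "T_base", "C_star", "F_star"),
              c("t0", "t0_chill", tri, "T_base", "C_star", "F_star"),
              function(p, env) .predict_sequential(env, p, "triangular", "none")),
    SQb  = sp("SQb", "CF",
              c("t0", "t0_chill", bel, "T_base", "C_star", "F_star"),
              c("t0", "t0_chill", bel, "T_base", "C_star", "F_star"),
              function(p, env) .predict_sequential(env, p, "bell", "none")),
    SM1  = sp("SM1", "CPF",
              c("t0", "t0_chill", tri, "T_base", "k", "C_star", "F_star"),
              c("t0", "t0_chill", tri, "T_base", "k", "C_star", "F_star"),
              function(p, env) .predict_sequential(env, p, "triangular", "m1")),
    SM1b = sp("SM1b", "CPF",
              c("t0", "t0_chill", bel, "T_base", "k", "C_star", "F_star"),
              c("t0", "t0_chill", bel, "T_base", "k", "C_star", "F_star"),
              function(p, env) .predict_sequential(env, p, "bell", "m1")),
    PA   = sp("PA", "CPF",
              c("t0", "t0_chill", tri, "T_base", "K_min", "C_star", "F_star"),
              c("t0", "t0_chill", tri, "T_base", "K_min", "C_star", "F_star"),
              function(p, env) .predict_parallel(env, p, "triangular", "none")),
    PAb  = sp("PAb", "CPF",
              c("t0", "t0_chill", bel, "T_base", "K_min", "C_star", "F_star"),
              c("t0", "t0_chill", bel, "T_base", "K_min", "C_star", "F_star"),
              function(p, env) .predict_parallel(env, p, "bell", "none")),
    PM1  = sp("PM1", "CPF",
              c("t0", "t0_chill", tri, "T_base", "K_min", "k", "C_star", "F_star"),
              c("t0", "t0_chill", tri, "T_base", "K_min", "k", "C_star", "F_star"),
              function(p, env) .predict_parallel(env, p, "triangular", "m1")),
    PM1b = sp("PM1b", "CPF",
              c("t0", "t0_chill", bel, "T_base", "K_min", "k", "C_star", "F_star"),
              c("t0", "t0_chill", bel, "T_base", "K_min", "k", "C_star", "F_star"),
              function(p, env) .predict_parallel(env, p, "bell", "m1")),
    UM1  = sp("UM1", "CPF",
              c("t0_chill", bel, "b_f", "c_f", "k", "w", "z"),
              c("t0_chill", bel, "b_f", "c_f", "k", "w", "z"),
              function(p, env) .predict_um1(env, p)),
    SGSI = sp("SGSI", "FPV",
              c("t0", "T_lo", "T_hi", "V_lo", "V_hi", "L_lo", "L_hi", "k", "thresh"),
              c("t0", "T_lo", "T_hi", "V_lo", "V_hi", "L_lo", "L_hi", "k", "thresh"),
              function(p, env) .predict_sgsi(env, p)),
    AGSI = sp("AGSI", "FPV",
              c("t0", "T_lo", "T_hi", "V_lo", "V_hi", "L_lo", "L_hi", "k", "F_star"),
              c("t0", "T_lo", "T_hi", "V_lo", "V_hi", "L_lo", "L_hi", "k", "F_gsi"),
              function(p, env) .predict_agsi(env, p)),

    CDD     = au("CDD", "C", c("t0", "T_base", "F_star"),
                 c("t0_aut", "T_base_aut", "F_aut"),
                 function(p, env) .predict_cdd(env, p, "linear")),
    CDDCO2  = au("CDDCO2", "C", c("t0", "T_base", "F_star", "c_co2"),
                 c("t0_aut", "T_base_aut", "F_aut", "c_co2"),
                 function(p, env) .predict_cdd(env, p, "linear", co2 = TRUE)),
    CDDs    = au("CDDs", "C", c("t0", "b_s", "c_s", "F_star"),
                 c("t0_aut", "b_s", "c_s", "F_aut"),
                 function(p, env) .predict_cdd(env, p, "sigmoid")),
    CDDsCO2 = au("CDDsCO2", "C", c("t0", "b_s", "c_s", "F_star", "c_co2"),
                 c("t0_aut", "b_s", "c_s", "F_aut", "c_co2"),
                 function(p, env) .predict_cdd(env, p, "sigmoid", co2 = TRUE)),
    CDDP    = au("CDDP", "CP", c("t0", "T_base", "F_star"),
                 c("t0_aut", "T_base_aut", "F_aut"),
                 function(p, env) .predict_cdd(env, p, "linear", "photoperiod")),
    CDDPCO2 = au("CDDPCO2", "CP", c("t0", "T_base", "F_star", "c_co2"),
                 c("t0_aut", "T_base_aut", "F_aut", "c_co2"),
                 function(p, env) .predict_cdd(env, p, "linear", "photoperiod",
                                               co2 = TRUE)),
    CDDM    = au("CDDM", "CM", c("t0", "T_base", "m", "F_star"),
                 c("t0_aut", "T_base_aut", "m", "F_aut"),
                 function(p, env) .predict_cdd(env, p, "linear", "water")),
    CDDMCO2 = au("CDDMCO2", "CM", c("t0", "T_base", "m", "F_star", "c_co2"),
                 c("t0_aut", "T_base_aut", "m", "F_aut", "c_co2"),
                 function(p, env) .predict_cdd(env, p, "linear", "water",
                                               co2 = TRUE)),
    PPM     = au("PPM", "PM", c("L_crit", "m", "F_star"),
                 c("L_crit", "m", "F_aut"),
                 function(p, env) .predict_ppm(env, p)),
    PPMCO2  = au("PPMCO2", "PM", c("L_crit", "m", "F_star", "c_co2"),
                 c("L_crit", "m", "F_aut", "c_co2"),
                 function(p, env) .predict_ppm(env, p, co2 = TRUE))
  )
})

#' The phenology model registry
#'
#' Nineteen spring and ten autumn process-based models, addressable by their
#' conventional abbreviations (case-insensitive): spring LIN, TT, TTs, PTT,
#' PTTs, M1, M1s, AT, SQ, SQb, SM1, SM1b, PA, PAb, PM1, PM1b, UM1, SGSI,
#' AGSI; autumn CDD, CDDCO2, CDDs, CDDsCO2, CDDP, CDDPCO2, CDDM, CDDMCO2,
#' PPM, PPMCO2. Each entry carries its season, driver letters (F forcing
#' temperature, C chilling temperature, P photoperiod, V vapour pressure
#' deficit, M moisture), ordered parameter names and default uniform search
#' bounds.
#'
#' @param season optional filter, `"spring"` or `"autumn"`.
#' @return named list of model specifications.
#' @export
pheno_models <- function(season = NULL) {
  r <- .registry
  if (!is.null(season)) r <- Filter(function(m) m$season == season, r)
  r
}

#' @rdname pheno_models
#' @param name model abbreviation (case-insensitive).
#' @export
pheno_model <- function(name) {
  i <- match(toupper(name), toupper(names(.registry)))
  if (is.na(i)) stop("unknown model: ", name)
  .registry[[i]]
}

#' Predict transition dates from a phenology model
#'
#' Forward-evaluates a named model on a collection of driver series. Returns
#' one predicted day of year per enclosure-year (integer for accumulation
#' models; continuous for LIN). `NA` is the no-transition sentinel: the
#' accumulated state never reached its requirement inside the window. It is
#' a value, not an error.
#'
#' @param model model abbreviation or a spec from [pheno_model()].
#' @param params named numeric vector covering the model's parameters.
#' @param drivers a [driver_series] or list of them, or a prebuilt
#'   environment from [build_model_env()].
#' @param temp_channel temperature driver channel (see [build_model_env()]).
#' @return named numeric vector of predicted DOYs (`NA` = sentinel).
#' @export
predict_phenology <- function(model, params, drivers, temp_channel = "air") {
  spec <- if (inherits(model, "pheno_model_spec")) model else pheno_model(model)
  miss <- setdiff(spec$params, names(params))
  if (length(miss)) stop("missing parameter(s) for ", spec$name, ": ",
                         paste(miss, collapse = ", "))
  env <- if (is.list(drivers) && !is.null(drivers$n_days)) drivers
         else build_model_env(drivers, temp_channel)
  if (spec$drivers %in% c("CM", "PM") && is.null(env$wtd))
    stop("driver error: water-table channel required for ", spec$name)
  p <- params[spec$params]
  setNames(spec$fn(p, env), env$labels)
}
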