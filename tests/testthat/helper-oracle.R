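# Independent day-by-day reference implementations of every model in the
# registry, written as plain scalar loops over one enclosure-year at a time.
# These deliberately share no code with the package's matrix/kernel
# evaluation path; they serve as the accumulation oracle.

oracle_env <- function(ds, channel = "air") {
  keep <- ds$doy <= 365
  doy <- ds$doy[keep]
  temp <- if (channel == "air") ds$t_air[keep]
          else ds$t_soil[keep, paste0("tsoil_", channel, "cm")]
  list(doy = doy, temp = temp, dayl = ds$daylength[keep],
       wtd = ds$wtd[keep],
       vpd = if (!is.null(ds$vpd)) ds$vpd[keep] else NULL,
       co2_gs = mean(ds$co2[keep][doy[] >= 120 & doy[] <= 280]))
}

.o_start <- function(e, t0) {
  # accumulation starts the day after t0: first index with doy > ceiling(t0)
  t <- ceiling(t0) + 1
  if (t <= e$doy[1]) return(1L)
  if (t > e$doy[length(e$doy)]) return(length(e$doy))
  which(e$doy >= t)[1]
}

.o_photo <- function(e, i, photo, p) {
  if (photo == "none") 1
  else if (photo == "ptt") e$dayl[i] / 24
  else (e$dayl[i] / 10)^p[["k"]]
}

.o_force <- function(e, i, form, p) {
  if (form == "linear") max(e$temp[i] - p[["T_base"]], 0)
  else 1 / (1 + exp(-p[["b_f"]] * (e$temp[i] - p[["c_f"]])))
}

.o_chill <- function(e, i, shape, p) {
  Tq <- e$temp[i]
  if (shape == "triangular") {
    if (Tq <= p[["T_min"]] || Tq >= p[["T_max"]]) 0
    else if (Tq <= p[["T_opt"]]) (Tq - p[["T_min"]]) / (p[["T_opt"]] - p[["T_min"]])
    else (p[["T_max"]] - Tq) / (p[["T_max"]] - p[["T_opt"]])
  } else {
    d <- Tq - p[["c_c"]]
    1 / (1 + exp(p[["a_c"]] * d^2 + p[["b_c"]] * d))
  }
}

oracle_tt_family <- function(p, e, form, photo) {
  s <- 0
  for (i in .o_start(e, p[["t0"]]):length(e$doy)) {
    s <- s + .o_force(e, i, form, p) * .o_photo(e, i, photo, p)
    if (s >= p[["F_star"]]) return(e$doy[i])
  }
  NA_real_
}

oracle_sequential <- function(p, e, shape, photo) {
  if (shape == "triangular" &&
      !(p[["T_min"]] < p[["T_opt"]] && p[["T_opt"]] < p[["T_max"]]))
    return(NA_real_)
  C <- 0; rel <- NA_integer_
  for (i in .o_start(e, p[["t0_chill"]]):length(e$doy)) {
    C <- C + .o_chill(e, i, shape, p)
    if (C >= p[["C_star"]]) { rel <- i; break }
  }
  if (is.na(rel)) return(NA_real_)
  start <- max(rel, .o_start(e, p[["t0"]]))
  s <- 0
  for (i in start:length(e$doy)) {
    s <- s + .o_force(e, i, "linear", p) * .o_photo(e, i, photo, p)
    if (s >= p[["F_star"]]) return(e$doy[i])
  }
  NA_real_
}

oracle_parallel <- function(p, e, shape, photo) {
  if (shape == "triangular" &&
      !(p[["T_min"]] < p[["T_opt"]] && p[["T_opt"]] < p[["T_max"]]))
    return(NA_real_)
  ic <- .o_start(e, p[["t0_chill"]])
  i0 <- .o_start(e, p[["t0"]])
  C <- 0; s <- 0
  for (i in seq_along(e$doy)) {
    if (i >= ic) C <- C + .o_chill(e, i, shape, p)
    if (i >= i0) {
      K <- if (p[["C_star"]] <= 0) 1
           else p[["K_min"]] + (1 - p[["K_min"]]) * min(1, C / p[["C_star"]])
      s <- s + K * .o_force(e, i, "linear", p) * .o_photo(e, i, photo, p)
      if (s >= p[["F_star"]]) return(e$doy[i])
    }
  }
  NA_real_
}

oracle_um1 <- function(p, e) {
  ic <- .o_start(e, p[["t0_chill"]])
  C <- 0; s <- 0
  for (i in ic:length(e$doy)) {
    C <- C + .o_chill(e, i, "bell", p)
    s <- s + .o_force(e, i, "sigmoid", p) * (e$dayl[i] / 10)^p[["k"]]
    if (s >= p[["w"]] * exp(-p[["z"]] * C)) return(e$doy[i])
  }
  NA_real_
}

oracle_at <- function(p, e) {
  i0 <- .o_start(e, p[["t0"]])
  Cd <- 0; g <- 0
  for (i in i0:length(e$doy)) {
    Cd <- Cd + (e$temp[i] < p[["T_base"]])
    g <- g + max(e$temp[i] - p[["T_base"]], 0)
    if (g >= p[["a"]] + p[["b"]] * exp(p[["c"]] * Cd)) return(e$doy[i])
  }
  NA_real_
}

oracle_lin <- function(p, e) {
  sel <- e$doy >= 1 & e$doy <= 120
  p[["a"]] + p[["b"]] * mean(e$temp[sel])
}

.o_gsi_day <- function(p, e, i) {
  ramp <- function(x, lo, hi) min(max((x - lo) / (hi - lo), 0), 1)
  ramp(e$temp[i], p[["T_lo"]], p[["T_hi"]]) *
    (1 - ramp(e$vpd[i], p[["V_lo"]], p[["V_hi"]])) *
    ramp(e$dayl[i], p[["L_lo"]], p[["L_hi"]])^p[["k"]]
}

oracle_sgsi <- function(p, e, w = 21L) {
  if (!(p[["T_lo"]] < p[["T_hi"]] && p[["V_lo"]] < p[["V_hi"]] &&
        p[["L_lo"]] < p[["L_hi"]])) return(NA_real_)
  ind <- vapply(seq_along(e$doy), function(i) .o_gsi_day(p, e, i), numeric(1))
  i0 <- .o_start(e, p[["t0"]])
  for (i in i0:length(e$doy)) {
    ma <- mean(ind[max(1, i - w + 1L):i])
    if (ma >= p[["thresh"]]) return(e$doy[i])
  }
  NA_real_
}

oracle_agsi <- function(p, e) {
  if (!(p[["T_lo"]] < p[["T_hi"]] && p[["V_lo"]] < p[["V_hi"]] &&
        p[["L_lo"]] < p[["L_hi"]])) return(NA_real_)
  s <- 0
  for (i in .o_start(e, p[["t0"]]):length(e$doy)) {
    s <- s + .o_gsi_day(p, e, i)
    if (s >= p[["F_star"]]) return(e$doy[i])
  }
  NA_real_
}

oracle_cdd <- function(p, e, form = "linear", weight = "none", co2 = FALSE) {
  thr <- p[["F_star"]]
  if (co2) thr <- max(p[["F_star"]] - p[["c_co2"]] * max(e$co2_gs - 400, 0),
                      0.05 * p[["F_star"]])
  s <- 0
  for (i in .o_start(e, p[["t0"]]):length(e$doy)) {
    r <- if (form == "linear") max(p[["T_base"]] - e$temp[i], 0)
         else 1 / (1 + exp(p[["b_s"]] * (e$temp[i] - p[["c_s"]])))
    if (weight == "photoperiod") r <- r * (1 - e$dayl[i] / 24)
    if (weight == "water") r <- r * max(1 + p[["m"]] * e$wtd[i], 0)
    s <- s + r
    if (s >= thr) return(e$doy[i])
  }
  NA_real_
}

oracle_ppm <- function(p, e, co2 = FALSE) {
  thr <- p[["F_star"]]
  if (co2) thr <- max(p[["F_star"]] - p[["c_co2"]] * max(e$co2_gs - 400, 0),
                      0.05 * p[["F_star"]])
  focal <- which(e$doy >= 1)
  i_sol <- focal[which.max(e$dayl[focal])]
  s <- 0
  for (i in i_sol:length(e$doy)) {
    s <- s + max(p[["L_crit"]] - e$dayl[i], 0) * max(1 + p[["m"]] * e$wtd[i], 0)
    if (s >= thr) return(e$doy[i])
  }
  NA_real_
}

# spring crossings are only valid budburst dates within DOY 1..243
.o_spring_window <- function(v) {
  if (!is.na(v) && (v < 1 || v > 243)) NA_real_ else v
}

# dispatch by registry name
oracle_predict <- function(model, p, ds, channel = "air") {
  e <- oracle_env(ds, channel)
  spring_cross <- c("TT", "TTs", "PTT", "PTTs", "M1", "M1s", "AT", "SQ",
                    "SQb", "SM1", "SM1b", "PA", "PAb", "PM1", "PM1b", "UM1",
                    "SGSI", "AGSI")
  v <- switch(model,
    LIN = oracle_lin(p, e),
    TT = oracle_tt_family(p, e, "linear", "none"),
    TTs = oracle_tt_family(p, e, "sigmoid", "none"),
    PTT = oracle_tt_family(p, e, "linear", "ptt"),
    PTTs = oracle_tt_family(p, e, "sigmoid", "ptt"),
    M1 = oracle_tt_family(p, e, "linear", "m1"),
    M1s = oracle_tt_family(p, e, "sigmoid", "m1"),
    AT = oracle_at(p, e),
    SQ = oracle_sequential(p, e, "triangular", "none"),
    SQb = oracle_sequential(p, e, "bell", "none"),
    SM1 = oracle_sequential(p, e, "triangular", "m1"),
    SM1b = oracle_sequential(p, e, "bell", "m1"),
    PA = oracle_parallel(p, e, "triangular", "none"),
    PAb = oracle_parallel(p, e, "bell", "none"),
    PM1 = oracle_parallel(p, e, "triangular", "m1"),
    PM1b = oracle_parallel(p, e, "bell", "m1"),
    UM1 = oracle_um1(p, e),
    SGSI = oracle_sgsi(p, e),
    AGSI = oracle_agsi(p, e),
    CDD = oracle_cdd(p, e),
    CDDCO2 = oracle_cdd(p, e, co2 = TRUE),
    CDDs = oracle_cdd(p, e, form = "sigmoid"),
    CDDsCO2 = oracle_cdd(p, e, form = "sigmoid", co2 = TRUE),
    CDDP = oracle_cdd(p, e, weight = "photoperiod"),
    CDDPCO2 = oracle_cdd(p, e, weight = "photoperiod", co2 = TRUE),
    CDDM = oracle_cdd(p, e, weight = "water"),
    CDDMCO2 = oracle_cdd(p, e, weight = "water", co2 = TRUE),
    PPM = oracle_ppm(p, e),
    PPMCO2 = oracle_ppm(p, e, co2 = TRUE),
    stop("no oracle for ", model))
  if (model %in% spring_cross) v <- .o_spring_window(v)
  v
}
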