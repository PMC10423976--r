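test_that("daily response rates match their definitions", {
  expect_equal(forcing_rate_linear(10, 5), 5)
  expect_equal(forcing_rate_linear(5, 5), 0)
  expect_equal(forcing_rate_linear(-3, 5), 0)
  expect_equal(forcing_rate_sigmoid(8, 0.5, 8), 0.5)
  expect_gt(forcing_rate_sigmoid(9, 50, 8), 0.999)
  expect_equal(forcing_rate_sigmoid(10, 0.5, 8), 1 / (1 + exp(-1)),
               tolerance = 1e-12)
  expect_equal(chilling_rate_triangular(0, -10, 0, 5), 1)
  expect_equal(chilling_rate_triangular(-10, -10, 0, 5), 0)
  expect_equal(chilling_rate_triangular(-5, -10, 0, 5), 0.5)
  expect_error(chilling_rate_triangular(0, 5, 0, -5), "T_min < T_opt < T_max")
  expect_equal(chilling_rate_bell(2, 1, 0, 2), 0.5)
  expect_lt(chilling_rate_bell(30, 1, 0, 2), 1e-8)
  expect_equal(chilling_rate_bell(0, 1, 0, 2), 1 / (1 + exp(4)),
               tolerance = 1e-12)
  expect_equal(photoperiod_multiplier(12, "PTT"), 0.5)
  expect_equal(photoperiod_multiplier(10, "M1", k = 3.7), 1)
  expect_equal(photoperiod_multiplier(15, "M1", k = 2), 2.25)
  expect_equal(cold_rate(3, "linear", T_base = 5), 2)
  expect_equal(cold_rate(7, "linear", T_base = 5), 0)
  expect_equal(cold_rate(4, "sigmoid", b_s = 1, c_s = 4), 0.5)
})

test_that("the CO2 offset lowers the senescence requirement as specified", {
  expect_equal(co2_threshold_offset(100, 0, 900), 100)
  expect_equal(co2_threshold_offset(100, 0.05, 400), 100)
  expect_equal(co2_threshold_offset(100, 0.05, 900), 75)
  # monotone non-increasing and floored at 5%
  v <- co2_threshold_offset(100, 0.05, seq(400, 3000, by = 100))
  expect_true(all(diff(v) <= 0))
  expect_gte(min(v), 5)
  expect_error(co2_threshold_offset(100, -0.1, 500), "c_co2")
})

test_that("unit accumulation crosses at t0 + F_star days", {
  d <- const_drivers(tair = 6) # T_base + 1 for T_base = 5
  p <- predict_phenology("TT", c(t0 = 30, T_base = 5, F_star = 10), d)
  expect_equal(unname(p), 40)
  # autumn: 2 cold degree days per day
  pa <- predict_phenology("CDD", c(t0 = 200, T_base = 4, F_star = 10),
                          const_drivers(tair = 2))
  expect_equal(unname(pa), 205)
})

test_that("degenerate chilling reduces sequential and parallel models to TT", {
  sim <- small_sim()
  drv <- sim$drivers[1:6]
  tt <- predict_phenology("TT", c(t0 = 30, T_base = 5, F_star = 120), drv)
  sq <- predict_phenology("SQ", c(t0 = 30, t0_chill = -100, T_min = -10,
                                  T_opt = 0, T_max = 10, T_base = 5,
                                  C_star = 0, F_star = 120), drv)
  pa <- predict_phenology("PA", c(t0 = 30, t0_chill = -100, T_min = -10,
                                  T_opt = 0, T_max = 10, T_base = 5,
                                  K_min = 0.3, C_star = 0, F_star = 120), drv)
  expect_identical(sq, tt)
  expect_identical(pa, tt)
})

test_that("the M1 photoperiod exponent nests the photoperiod-free models", {
  sim <- small_sim()
  drv <- sim$drivers[1:6]
  tt <- predict_phenology("TT", c(t0 = 20, T_base = 4, F_star = 100), drv)
  m1 <- predict_phenology("M1", c(t0 = 20, T_base = 4, k = 0, F_star = 100), drv)
  expect_identical(m1, tt)
  sq_par <- c(t0 = 20, t0_chill = -100, T_min = -20, T_opt = -5, T_max = 10,
              T_base = 4, C_star = 30, F_star = 100)
  sm1 <- predict_phenology("SM1", c(sq_par, k = 0), drv)
  sq <- predict_phenology("SQ", sq_par, drv)
  expect_identical(sm1, sq)
  pa_par <- c(sq_par, K_min = 0.2)
  pm1 <- predict_phenology("PM1", c(pa_par, k = 0), drv)
  pa <- predict_phenology("PA", pa_par, drv)
  expect_identical(pm1, pa)
})

test_that("uniform warming never delays forcing models nor advances cold models", {
  sim <- small_sim()
  set.seed(7)
  for (model in c("TT", "PTT", "M1")) {
    spec <- pheno_model(model)
    for (i in 1:5) {
      par <- random_params(spec)
      drv <- sim$drivers[1:4]
      warm <- lapply(drv, function(d) { d$t_air <- d$t_air + 2; d })
      p0 <- predict_phenology(spec, par, drv)
      p1 <- predict_phenology(spec, par, warm)
      ok <- !is.na(p0) & !is.na(p1)
      expect_true(all(p1[ok] <= p0[ok]))
    }
  }
  for (model in c("CDD", "CDDs", "CDDP", "CDDM")) {
    spec <- pheno_model(model)
    for (i in 1:5) {
      par <- random_params(spec)
      drv <- sim$drivers[1:4]
      warm <- lapply(drv, function(d) { d$t_air <- d$t_air + 2; d })
      p0 <- predict_phenology(spec, par, drv)
      p1 <- predict_phenology(spec, par, warm)
      ok <- !is.na(p0) & !is.na(p1)
      expect_true(all(p1[ok] >= p0[ok]))
    }
  }
})

test_that("raising the forcing requirement never advances a prediction", {
  sim <- small_sim()
  drv <- sim$drivers[1:4]
  set.seed(11)
  for (model in c("TT", "TTs", "PTT", "M1", "AGSI")) {
    spec <- pheno_model(model)
    for (i in 1:4) {
      par <- random_params(spec)
      par2 <- par; par2[["F_star"]] <- par[["F_star"]] * 1.5
      p1 <- predict_phenology(spec, par, drv)
      p2 <- predict_phenology(spec, par2, drv)
      ok <- !is.na(p1) & !is.na(p2)
      expect_true(all(p2[ok] >= p1[ok]))
    }
  }
})

test_that("every registered model evaluates on in-bounds parameters", {
  sim <- small_sim()
  drv <- sim$drivers[1:4]
  set.seed(5)
  for (spec in pheno_models()) {
    for (i in 1:5) {
      p <- predict_phenology(spec, random_params(spec), drv)
      expect_length(p, 4)
      expect_true(is.numeric(p))
    }
  }
})

test_that("elevated CO2 never delays a CO2-variant prediction", {
  sim <- small_sim()
  labs <- vapply(sim$drivers, function(d) d$enclosure, "")
  ele <- sim$drivers[labs == "E02"] # elevated enclosure
  amb <- lapply(ele, function(d) { d$co2 <- rep(400, length(d$co2)); d })
  for (model in c("CDDCO2", "CDDsCO2", "CDDPCO2", "CDDMCO2", "PPMCO2")) {
    spec <- pheno_model(model)
    set.seed(13)
    for (i in 1:5) {
      par <- random_params(spec)
      p_a <- predict_phenology(spec, par, amb)
      p_e <- predict_phenology(spec, par, ele)
      ok <- !is.na(p_a) & !is.na(p_e)
      expect_true(all(p_e[ok] <= p_a[ok]))
    }
  }
})

test_that("CO2 variants with c_co2 = 0 equal their base models", {
  sim <- small_sim()
  drv <- sim$drivers[c(2, 4, 6, 8, 10)] # elevated enclosures
  pairs <- list(c("CDDCO2", "CDD"), c("CDDsCO2", "CDDs"), c("CDDPCO2", "CDDP"),
                c("CDDMCO2", "CDDM"), c("PPMCO2", "PPM"))
  set.seed(17)
  for (pr in pairs) {
    base <- pheno_model(pr[2])
    for (i in 1:5) {
      par <- random_params(base)
      expect_identical(predict_phenology(pr[1], c(par, c_co2 = 0), drv),
                       predict_phenology(pr[2], par, drv))
    }
  }
})

test_that("missing driver channels raise driver errors", {
  tab <- const_driver_table(8)
  tab$wtd_cm <- NA_real_
  d <- build_driver_series(tab)
  expect_error(predict_phenology("CDDM", c(t0 = 200, T_base = 10, m = 0.01,
                                           F_star = 50), d),
               "driver error")
  tab2 <- const_driver_table(8)
  tab2$rh_pct <- NULL
  d2 <- build_driver_series(tab2)
  expect_error(predict_phenology("SGSI", random_params(pheno_model("SGSI")), d2),
               "driver error")
})

test_that("the registry is complete and parameter counts match the suite", {
  counts <- c(LIN = 2, TT = 3, TTs = 4, PTT = 3, PTTs = 4, M1 = 4, M1s = 5,
              AT = 5, SQ = 8, SQb = 8, SM1 = 9, SM1b = 9, PA = 9, PAb = 9,
              PM1 = 10, PM1b = 10, UM1 = 9, SGSI = 9, AGSI = 9,
              CDD = 3, CDDCO2 = 4, CDDs = 4, CDDsCO2 = 5, CDDP = 3,
              CDDPCO2 = 4, CDDM = 4, CDDMCO2 = 5, PPM = 3, PPMCO2 = 4)
  expect_setequal(names(pheno_models()), names(counts))
  for (nm in names(counts))
    expect_length(pheno_model(nm)$params, counts[[nm]])
  expect_equal(pheno_model("sm1b")$name, "SM1b") # case-insensitive lookup
  expect_length(pheno_models("autumn"), 10)
  expect_error(pheno_model("XYZ"), "unknown model")
})
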