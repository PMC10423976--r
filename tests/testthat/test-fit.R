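fake_fit <- function(model, aic, obs) {
  structure(list(model = model, aic = aic, rmse = 1, k_params = 3,
                 observed = obs), class = "pheno_fit")
}

test_that("the RMSE cost penalizes sentinels and matches hand arithmetic", {
  expect_equal(cost_rmse(c(100, 110), c(100, 110)), 0)
  expect_equal(cost_rmse(c(100, 110), c(102, 108)), 2)
  expect_gt(cost_rmse(c(100, 110), c(100, NA)), 5000)
  expect_error(cost_rmse(numeric(), numeric()), "empty")
})

test_that("the AIC follows 2k + n log(SSE/n)", {
  obs <- rep(0, 10)
  pred <- rep(-exp(1), 10) # SSE = 10 e^2
  expect_equal(compute_aic(obs, pred, k = 3), 26, tolerance = 1e-12)
  set.seed(1)
  o <- rnorm(37, 120, 5); p <- o + rnorm(37, 0, 3)
  direct <- 2 * 4 + 37 * log(sum((o - p)^2) / 37)
  expect_equal(compute_aic(o, p, k = 4), direct, tolerance = 1e-10)
  # changing only k shifts the AIC by exactly 2 dk
  expect_equal(compute_aic(o, p, k = 9) - compute_aic(o, p, k = 4), 10)
  expect_warning(a0 <- compute_aic(o, o, k = 2), "zero error")
  expect_true(is.finite(a0))
})

test_that("AIC ordering is invariant to a common shift of all dates", {
  set.seed(2)
  o <- rnorm(30, 120, 6)
  p1 <- o + rnorm(30, 0, 2); p2 <- o + rnorm(30, 0, 4)
  d0 <- compute_aic(o, p1, 3) - compute_aic(o, p2, 3)
  d1 <- compute_aic(o + 50, p1 + 50, 3) - compute_aic(o + 50, p2 + 50, 3)
  expect_equal(d0, d1, tolerance = 1e-10)
})

test_that("noise-free thermal-time data are recovered to sub-day RMSE", {
  sim <- full_sim()
  tr <- simulate_transitions_process(sim$drivers, "TT", tt_truth, seed = 4)
  fit <- pheno_fit("TT", tr, sim$drivers,
                   config = fit_config(n_chains = 5, n_iter = 2000, seed = 11))
  expect_lte(fit$rmse, 0.5)
  expect_equal(fit$k_params, 3)
  expect_equal(fit$aic,
               compute_aic(tr$doy, unname(fit$predicted), 3), tolerance = 1e-10)
})

test_that("refitting with the same seed is bit-identical", {
  sim <- small_sim()
  tr <- simulate_transitions_process(sim$drivers, "TT", tt_truth, seed = 4)
  cfg <- fit_config(n_chains = 2, n_iter = 600, seed = 42)
  f1 <- pheno_fit("TT", tr, sim$drivers, config = cfg)
  f2 <- pheno_fit("TT", tr, sim$drivers, config = cfg)
  expect_identical(f1$par, f2$par)
  expect_identical(f1$aic, f2$aic)
  expect_identical(f1$chain_values, f2$chain_values)
})

test_that("the fitted RMSE tracks the generating noise floor", {
  rmses <- vapply(1:10, function(r) {
    sim <- simulate_drivers(n_years = 3, seed = 30 + r)
    tr <- simulate_transitions_process(sim$drivers, "TT", tt_truth,
                                       noise_sd = 3, seed = 60 + r)
    pheno_fit("TT", tr, sim$drivers,
              config = fit_config(n_chains = 3, n_iter = 1000,
                                  seed = 90 + r))$rmse
  }, numeric(1))
  expect_true(all(rmses >= 2 & rmses <= 4.5))
})

test_that("model ranking applies the delta-AIC support classes", {
  obs <- data.frame(enclosure = "A", year = 2019, doy = 120)
  rk <- rank_models(list(fake_fit("m1", 100, obs), fake_fit("m2", 101.5, obs),
                         fake_fit("m3", 112, obs)))
  expect_equal(rk$delta_aic, c(0, 1.5, 12))
  expect_equal(as.character(rk$support), c("equivalent", "equivalent", "none"))
  one <- rank_models(list(fake_fit("m1", 57.3, obs)))
  expect_equal(one$delta_aic, 0)
  expect_equal(as.character(one$support), "equivalent")
  tie <- rank_models(list(fake_fit("m1", 50, obs), fake_fit("m2", 50, obs)))
  expect_equal(tie$delta_aic, c(0, 0))
  obs2 <- data.frame(enclosure = "B", year = 2019, doy = 130)
  expect_error(rank_models(list(fake_fit("m1", 1, obs), fake_fit("m2", 2, obs2))),
               "comparability")
})

test_that("observations without matching drivers raise a pairing error", {
  sim <- small_sim()
  tr <- data.frame(enclosure = "ZZ", year = 1999, doy = 120)
  expect_error(pheno_fit("TT", tr, sim$drivers,
                         config = fit_config(n_chains = 1, n_iter = 10)),
               "pairing error")
})

test_that("applying fitted parameters reproduces the training RMSE exactly", {
  sim <- small_sim()
  tr <- simulate_transitions_process(sim$drivers, "TT", tt_truth,
                                     noise_sd = 2, seed = 8)
  fit <- pheno_fit("TT", tr, sim$drivers,
                   config = fit_config(n_chains = 2, n_iter = 800, seed = 5))
  ap <- apply_fitted(fit, tr, sim$drivers)
  expect_false(ap$skipped)
  expect_identical(ap$rmse, fit$rmse)
})

test_that("held-out sites generated from the same truth stay near training error", {
  sim <- simulate_drivers(n_years = 3, seed = 51)
  tr <- simulate_transitions_process(sim$drivers, "TT", tt_truth,
                                     noise_sd = 2, seed = 52)
  fit <- pheno_fit("TT", tr, sim$drivers,
                   config = fit_config(n_chains = 3, n_iter = 1200, seed = 53))
  ratios <- vapply(1:3, function(r) {
    hold <- simulate_drivers(n_years = 2, seed = 60 + r)
    thold <- simulate_transitions_process(hold$drivers, "TT", tt_truth,
                                          noise_sd = 2, seed = 70 + r)
    apply_fitted(fit, thold, hold$drivers)$rmse / fit$rmse
  }, numeric(1))
  expect_lt(mean(ratios), 2)
})

test_that("water-table models are skipped, not crashed, where the channel is absent", {
  tab <- const_driver_table(8)
  tab$wtd_cm <- NA_real_
  d <- build_driver_series(tab)
  tr <- data.frame(enclosure = "X1", year = 2019, doy = 280)
  ap <- apply_fitted("CDDM", tr, d,
                     params = c(t0 = 200, T_base = 10, m = 0.01, F_star = 50))
  expect_true(ap$skipped)
  expect_match(ap$notice, "water-table")
})

test_that("identical temperature channels give identical depth-scan AICs", {
  d <- build_driver_series(const_driver_table(tair = 10 + 8 * sin(2 * pi * (1:730) / 365)))
  tr <- data.frame(enclosure = "X1", year = 2019, doy = 130)
  tab <- compare_driver_depths("TT", tr, d, channels = c("air", "0"),
                               config = fit_config(n_chains = 1, n_iter = 300,
                                                   seed = 2))
  # the constant-profile fixture copies air temperature to every soil depth
  expect_equal(tab$aic[1], tab$aic[2], tolerance = 1e-12)
  tab2 <- compare_driver_depths("TT", tr, d, channels = c("air", "999"),
                                config = fit_config(n_chains = 1, n_iter = 100,
                                                    seed = 2))
  expect_equal(tab2$status, c("ok", "absent"))
})

test_that("nested pairs on noise-free data favour the simpler model", {
  sim <- small_sim()
  tr <- simulate_transitions_process(sim$drivers, "TT", tt_truth, seed = 77)
  fT <- pheno_fit("TT", tr, sim$drivers,
                  config = fit_config(n_chains = 5, n_iter = 2000, seed = 78))
  fM <- pheno_fit("M1", tr, sim$drivers,
                  config = fit_config(n_chains = 5, n_iter = 2000, seed = 79))
  rk <- rank_models(list(fT, fM))
  expect_lt(rk$delta_aic[rk$model == "TT"], 2)
})
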