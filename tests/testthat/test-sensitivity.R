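meta10 <- function() {
  enclosure_metadata(sprintf("E%02d", 1:10),
                     target_warming = rep(c(0, 2.25, 4.5, 6.75, 9), each = 2),
                     co2_treatment = rep(c("ambient", "elevated"), 5))
}

test_that("noise-free linear data are recovered exactly with CO2 dropped", {
  md <- meta10()
  g <- expand.grid(enclosure = md$enclosure, year = 2016:2018,
                   stringsAsFactors = FALSE)
  dT <- md$measured_warming[match(g$enclosure, md$enclosure)]
  tr <- data.frame(g, pft = "DN", season = "spring", doy = 118 - 1.6 * dT)
  s <- fit_sensitivity_lme(tr, md, "spring", "DN")
  expect_equal(unname(coef(s)[["dtemp"]]), -1.6, tolerance = 1e-8)
  expect_equal(unname(coef(s)[["(Intercept)"]]), 118, tolerance = 1e-8)
  expect_false(any(grepl("co2", s$coefficients$term)))
})

test_that("with no year variance the mixed fit matches ordinary least squares", {
  md <- meta10()
  set.seed(31)
  g <- expand.grid(enclosure = md$enclosure, year = 2016:2020,
                   stringsAsFactors = FALSE)
  dT <- md$measured_warming[match(g$enclosure, md$enclosure)]
  tr <- data.frame(g, pft = "DN", season = "spring",
                   doy = 120 - 1.4 * dT + rnorm(nrow(g), 0, 4))
  s <- fit_sensitivity_lme(tr, md, "spring", "DN", reduce = FALSE,
                           formula_terms = "dtemp")
  ols <- lm(doy ~ dtemp, data = transform(tr, dtemp = dT))
  expect_equal(unname(coef(s)[["dtemp"]]), unname(coef(ols)[["dtemp"]]),
               tolerance = 1e-6)
})

test_that("the mixed-model route agrees with an independent mixed-model fitter", {
  md <- meta10()
  sim_tr <- simulate_transitions_lme(md, 2016:2020, "DN", "autumn", seed = 5)
  s <- fit_sensitivity_lme(sim_tr, md, "autumn", "DN", reduce = FALSE,
                           formula_terms = "dtemp*co2")
  d <- sim_tr
  d$dtemp <- md$measured_warming[match(d$enclosure, md$enclosure)]
  d$co2 <- as.numeric(md$co2_treatment[match(d$enclosure, md$enclosure)] == "elevated")
  lmer_fit <- lme4::lmer(doy ~ dtemp * co2 + (1 | year), data = d, REML = TRUE)
  expect_equal(unname(coef(s)[["dtemp"]]),
               unname(lme4::fixef(lmer_fit)[["dtemp"]]), tolerance = 1e-3)
  expect_equal(unname(coef(s)[["co2"]]),
               unname(lme4::fixef(lmer_fit)[["co2"]]), tolerance = 1e-3)
})

test_that("slope estimates are invariant to shifting all dates", {
  md <- meta10()
  tr <- simulate_transitions_lme(md, 2016:2019, "SH", "autumn", seed = 8)
  s1 <- fit_sensitivity_lme(tr, md, "autumn", "SH")
  tr2 <- tr; tr2$doy <- tr2$doy + 40
  s2 <- fit_sensitivity_lme(tr2, md, "autumn", "SH")
  expect_equal(coef(s1)[["dtemp"]], coef(s2)[["dtemp"]], tolerance = 1e-6)
})

test_that("degenerate designs raise informative errors", {
  md <- meta10()
  tr <- simulate_transitions_lme(md, 2016:2017, "DN", "spring", seed = 2)
  expect_error(fit_sensitivity_lme(tr[tr$year == 2016, ], md, "spring", "DN"),
               "two years")
  ctrl <- md$enclosure[md$target_warming == 0]
  expect_error(fit_sensitivity_lme(tr[tr$enclosure %in% ctrl, ], md,
                                   "spring", "DN"),
               "rank-deficiency")
  expect_error(fit_sensitivity_lme(tr, md, "autumn", "DN"), "no observations")
})

test_that("randomly permuted CO2 labels are dropped at the nominal rate", {
  md <- meta10()
  kept <- 0L
  for (r in 1:20) {
    md2 <- md
    set.seed(100 + r)
    md2$co2_treatment <- sample(md$co2_treatment)
    tr <- simulate_transitions_lme(
      md, 2016:2020, "SH", "autumn", seed = 300 + r,
      coefficients = list(intercept = 288, temp = 3, co2 = 0,
                          interaction = 0, resid_sd = 6))
    s <- fit_sensitivity_lme(tr, md2, "autumn", "SH")
    if (any(grepl("co2", s$coefficients$term))) kept <- kept + 1L
  }
  expect_lte(kept, 4) # >= 90% dropped, with head-room for 20 draws
})

test_that("doubling the residual noise roughly doubles the slope SE", {
  md <- meta10()
  se_at <- function(sd0, r) {
    tr <- simulate_transitions_lme(
      md, 2016:2020, "DN", "spring", seed = 400 + r, year_sd = 0,
      coefficients = list(intercept = 118, temp = -1.6, co2 = 0,
                          interaction = 0, resid_sd = sd0))
    s <- fit_sensitivity_lme(tr, md, "spring", "DN", reduce = FALSE,
                             formula_terms = "dtemp")
    s$coefficients$se[s$coefficients$term == "dtemp"]
  }
  r1 <- mean(vapply(1:15, function(r) se_at(3, r), numeric(1)))
  r2 <- mean(vapply(1:15, function(r) se_at(6, r), numeric(1)))
  expect_gt(r2 / r1, 1.4)
  expect_lt(r2 / r1, 2.6)
})

test_that("per-year sensitivities recover simple structures", {
  md <- meta10()
  g <- expand.grid(enclosure = md$enclosure, year = 2016:2017,
                   stringsAsFactors = FALSE)
  dT <- md$measured_warming[match(g$enclosure, md$enclosure)]
  tr <- data.frame(g, pft = "DN", season = "spring", doy = 120 - 2 * dT)
  py <- per_year_sensitivity(tr, md, "spring", "DN")
  expect_equal(py$slope, c(-2, -2), tolerance = 1e-10)
  trc <- transform(tr, doy = 117)
  expect_equal(per_year_sensitivity(trc, md, "spring", "DN")$slope, c(0, 0),
               tolerance = 1e-10)
  # fewer than three enclosures in a year -> flagged undefined
  py2 <- per_year_sensitivity(tr[c(1, 2, 11:20), ], md, "spring", "DN")
  expect_true(is.na(py2$slope[py2$year == 2016]))
})

test_that("season extension is the autumn minus the spring slope", {
  expect_equal(season_extension(-1.1, 2.1), 3.2)
  expect_equal(season_extension(0, 0), 0)
  sp <- data.frame(year = 2016:2018, slope = c(-1, -1.5, -2))
  au <- data.frame(year = 2016:2018, slope = c(2, 1, 3))
  expect_equal(unname(season_extension(sp, au)), c(3, 2.5, 5))
  expect_error(season_extension(sp, au[-1, ]), "mismatched")
})

test_that("per-year spring slopes from the generator average near the truth", {
  md <- meta10()
  slopes <- unlist(lapply(1:5, function(r) {
    tr <- simulate_transitions_lme(
      md, 2016:2020, "DN", "spring", seed = 500 + r,
      coefficients = list(intercept = 118, temp = -1.1, co2 = 0,
                          interaction = 0, resid_sd = 4))
    per_year_sensitivity(tr, md, "spring", "DN")$slope
  }))
  expect_equal(mean(slopes), -1.1, tolerance = 3 * sd(slopes) / sqrt(length(slopes)))
})
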