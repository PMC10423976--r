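# Shared fixtures, generated in code and cached for the session.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, .fixture_cache)) assign(key, force(expr), .fixture_cache)
  get(key, .fixture_cache)
}

small_sim <- function() cached("small_sim", simulate_drivers(n_years = 2, seed = 42))
full_sim <- function() cached("full_sim", simulate_drivers(n_years = 5, seed = 42))

# a canonical daily table with controllable air temperature, one enclosure,
# spanning two calendar years (one focal year with full window)
const_driver_table <- function(tair = 10, year = 2019, enclosure = "X1",
                               wtd = -10, co2 = 400, rh = 70) {
  dates <- seq(as.Date(sprintf("%d-01-01", year - 1)),
               as.Date(sprintf("%d-12-31", year)), "day")
  n <- length(dates)
  tv <- if (length(tair) == 1) rep(tair, n) else tair
  df <- data.frame(enclosure = enclosure, date = dates, tair_c = tv,
                   stringsAsFactors = FALSE)
  for (d in c(0, 5, 10, 20, 30, 40, 50, 100, 200))
    df[[paste0("tsoil_", d, "cm")]] <- tv
  df$wtd_cm <- wtd; df$co2_ppm <- co2; df$rh_pct <- rh
  df
}

const_drivers <- function(...) build_driver_series(const_driver_table(...))[[1]]

# truth parameter sets used by the synthetic process experiments: a plain
# thermal-time truth, and a sequential truth whose chilling requirement
# binds in the warmest enclosures (wide falling edge keeps slow chilling
# going into spring, so strong warming delays chilling release enough to
# offset its forcing advance)
tt_truth <- c(t0 = 30, T_base = 5, F_star = 120)
sm1_truth <- c(t0 = 1, t0_chill = -60, T_min = -30, T_opt = -12, T_max = 20,
               T_base = 5, k = 1, C_star = 92, F_star = 15)
cdd_truth <- c(t0 = 230, T_base = 16, F_star = 120)
cddco2_truth <- c(t0 = 230, T_base = 16, F_star = 120, c_co2 = 0.06)

# draw a random in-bounds parameter vector for a model spec
random_params <- function(spec) {
  setNames(spec$lower + runif(length(spec$lower)) * (spec$upper - spec$lower),
           spec$params)
}
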