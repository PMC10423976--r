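#' Fitting configuration
#'
#' Controls for [pheno_fit()]. Defaults mirror the full estimation protocol
#' (25 parallel chains of 40,000 simulated-annealing iterations each); tests
#' and examples use far smaller presets.
#'
#' @param n_chains number of independent annealing chains (>= 1).
#' @param n_iter iterations per chain.
#' @param seed master seed; per-chain sub-seeds are derived from it.
#' @param penalty days substituted for a no-transition sentinel prediction
#'   before squaring in the cost, so parameter vectors that fail to predict
#'   a transition are dominated.
#' @param bounds optional named list with `lower`/`upper` named vectors
#'   overriding the registry defaults for a subset of parameters.
#' @param sse_floor floor applied to a zero error sum of squares in the AIC
#'   (a warning is emitted when it binds).
#' @return a `fit_config` list.
#' @export
fit_config <- function(n_chains = 25, n_iter = 40000, seed = 1,
                       penalty = 9999, bounds = NULL, sse_floor = 1e-8) {
  stopifnot(n_chains >= 1, n_iter >= 1)
  structure(list(n_chains = as.integer(n_chains), n_iter = as.integer(n_iter),
                 seed = as.integer(seed), penalty = penalty, bounds = bounds,
                 sse_floor = sse_floor), class = "fit_config")
}

#' Root-mean-square error with sentinel penalty
#'
#' @param observed,predicted equal-length numeric vectors of transition DOYs;
#'   `NA` predictions (no-transition sentinels) are replaced by `penalty`
#'   before squaring.
#' @param penalty substitute value for sentinels.
#' @return RMSE in days.
#' @export
cost_rmse <- function(observed, predicted, penalty = 9999) {
  if (!length(observed)) stop("empty observation vector")
  if (length(observed) != length(predicted))
    stop("observed and predicted must have equal length")
  predicted[is.na(predicted)] <- penalty
  sqrt(mean((observed - predicted)^2))
}

#' AIC for a phenology model fit
#'
#' `AIC = 2k + n log(SSE/n)` with the natural logarithm, `n` the number of
#' observations and `k` the model's parameter count. A zero SSE is floored
#' at `sse_floor` with a warning.
#'
#' @param observed,predicted transition DOY vectors (sentinel `NA`
#'   predictions are replaced by `penalty`).
#' @param k parameter count.
#' @param penalty sentinel substitute (as in [cost_rmse()]).
#' @param sse_floor guard for perfect fits.
#' @return AIC value.
#' @export
compute_aic <- function(observed, predicted, k, penalty = 9999,
                        sse_floor = 1e-8) {
  n <- length(observed)
  if (n < 1) stop("need at least one observation")
  predicted[is.na(predicted)] <- penalty
  sse <- sum((observed - predicted)^2)
  if (sse <= 0) {
    warning("zero error sum of squares; floored at ", sse_floor)
    sse <- sse_floor
  }
  2 * k + n * log(sse / n)
}

.match_drivers <- function(transitions, drivers) {
  keys <- vapply(drivers, function(d) paste(d$enclosure, d$year, sep = "."),
                 character(1))
  want <- paste(transitions$enclosure, transitions$year, sep = ".")
  m <- match(want, keys)
  if (anyNA(m))
    stop("pairing error: no driver series for observation(s) ",
         paste(unique(want[is.na(m)]), collapse = ", "))
  drivers[m]
}

#' Fit a phenology model by simulated annealing
#'
#' Estimates a model's parameters against observed transition dates by
#' minimizing the RMSE (with sentinel penalty) over the model's bounded
#' parameter space, running `n_chains` independent annealing chains from
#' uniform starts and keeping the chain with the lowest AIC (for a fixed
#' model this is the lowest-RMSE chain). Fully deterministic given
#' `config$seed`: chain sub-seeds are drawn once from the master seed, so
#' chains are reproducible and order-independent.
#'
#' @param model model abbreviation or [pheno_model()] spec.
#' @param transitions data frame of observations with columns `enclosure`,
#'   `year`, `doy` (and optionally `pft`, `season`, used for bookkeeping).
#' @param drivers list of [driver_series]; every observation must have a
#'   matching (enclosure, year) series.
#' @param temp_channel temperature driver channel (`"air"` or soil depth cm).
#' @param config a [fit_config()].
#' @return object of class `pheno_fit` with components `model`, `par`,
#'   `predicted`, `observed`, `rmse`, `aic`, `n_obs`, `k_params`,
#'   `chain_values` (best cost per chain), `chain_seeds`, `temp_channel`,
#'   `config`. Methods: `print`, `summary`, `coef`, `predict`, `fitted`,
#'   `residuals`, `plot`.
#' @examples
#' \donttest{
#' sim <- simulate_drivers(n_years = 2, seed = 1)
#' tr <- simulate_transitions_process(sim$drivers, "TT",
#'   c(t0 = 30, T_base = 5, F_star = 120), seed = 2)
#' fit <- pheno_fit("TT", tr, sim$drivers,
#'                  config = fit_config(n_chains = 3, n_iter = 800, seed = 7))
#' fit
#' }
#' @export
pheno_fit <- function(model, transitions, drivers, temp_channel = "air",
                      config = fit_config()) {
  spec <- if (inherits(model, "pheno_model_spec")) model else pheno_model(model)
  lower <- spec$lower; upper <- spec$upper
  if (!is.null(config$bounds)) {
    if (!is.null(config$bounds$lower)) {
      nm <- intersect(names(config$bounds$lower), names(lower))
      lower[nm] <- config$bounds$lower[nm]
    }
    if (!is.null(config$bounds$upper)) {
      nm <- intersect(names(config$bounds$upper), names(upper))
      upper[nm] <- config$bounds$upper[nm]
    }
  }
  matched <- .match_drivers(transitions, drivers)
  env <- build_model_env(matched, temp_channel)
  obs <- transitions$doy
  cost <- function(par) {
    names(par) <- spec$params
    cost_rmse(obs, spec$fn(par, env), penalty = config$penalty)
  }
  set.seed(config$seed)
  chain_seeds <- sample.int(.Machine$integer.max - 1L, config$n_chains)
  chains <- lapply(chain_seeds, function(s)
    anneal_minimize(cost, lower, upper, n_iter = config$n_iter, seed = s))
  values <- vapply(chains, `[[`, numeric(1), "value")
  best <- chains[[which.min(values)]]
  par <- setNames(best$par, spec$params)
  predicted <- setNames(spec$fn(par, env), env$labels)
  k <- length(spec$params)
  aic <- compute_aic(obs, predicted, k, penalty = config$penalty,
                     sse_floor = config$sse_floor)
  structure(list(model = spec$name, season = spec$season, par = par,
                 lower = lower, upper = upper,
                 predicted = predicted, observed = transitions,
                 rmse = cost_rmse(obs, predicted, penalty = config$penalty),
                 aic = aic, n_obs = length(obs), k_params = k,
                 chain_values = values, chain_seeds = chain_seeds,
                 temp_channel = as.character(temp_channel), config = config),
            class = "pheno_fit")
}

#' @export
print.pheno_fit <- function(x, ...) {
  cat(sprintf("Phenology model fit: %s (%s, %d parameters)\n",
              x$model, x$season, x$k_params))
  cat(sprintf("  %d observations, temperature channel '%s'\n",
              x$n_obs, x$temp_channel))
  cat(sprintf("  RMSE %.3f days, AIC %.2f (%d chains x %d iterations)\n",
              x$rmse, x$aic, x$config$n_chains, x$config$n_iter))
  invisible(x)
}

#' @export
summary.pheno_fit <- function(object, ...) {
  out <- list(fit = object,
              par_table = data.frame(parameter = names(object$par),
                                     estimate = unname(object$par),
                                     lower = unname(object$lower),
                                     upper = unname(object$upper)),
              chain_spread = range(object$chain_values))
  class(out) <- "summary.pheno_fit"
  out
}

#' @export
print.summary.pheno_fit <- function(x, ...) {
  print(x$fit)
  cat("Parameters (with search bounds):\n")
  print(x$par_table, row.names = FALSE, digits = 4)
  cat(sprintf("Chain best costs: %.3f .. %.3f days\n",
              x$chain_spread[1], x$chain_spread[2]))
  invisible(x)
}

#' @export
coef.pheno_fit <- function(object, ...) object$par

#' @export
fitted.pheno_fit <- function(object, ...) object$predicted

#' @export
residuals.pheno_fit <- function(object, ...) {
  setNames(object$observed$doy - unname(object$predicted),
           names(object$predicted))
}

#' @param object,newdata a fitted model and (optionally) a new list of
#'   [driver_series]; with `newdata = NULL` the training predictions are
#'   returned.
#' @rdname pheno_fit
#' @export
predict.pheno_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$predicted)
  predict_phenology(object$model, object$par, newdata,
                    temp_channel = object$temp_channel)
}

#' @param x a `pheno_fit`.
#' @param ... passed to `plot`.
#' @rdname pheno_fit
#' @export
plot.pheno_fit <- function(x, ...) {
  obs <- x$observed$doy
  pred <- unname(x$predicted)
  lim <- range(c(obs, pred), na.rm = TRUE) + c(-3, 3)
  plot(obs, pred, xlab = "observed DOY", ylab = "predicted DOY",
       xlim = lim, ylim = lim,
       main = sprintf("%s: RMSE %.2f d", x$model, x$rmse), ...)
  abline(0, 1, lty = 2)
  invisible(x)
}

#' Serialize a fit to JSON
#'
#' Writes a `pheno_fit` (parameters, bounds, predictions, seeds and
#' configuration) to a JSON file for reproducibility.
#'
#' @param fit a [pheno_fit()] result.
#' @param path output file.
#' @export
write_fit_json <- function(fit, path) {
  x <- fit[c("model", "season", "par", "lower", "upper", "rmse", "aic",
             "n_obs", "k_params", "chain_values", "chain_seeds",
             "temp_channel")]
  x$predicted <- as.list(fit$predicted)
  x$config <- unclass(fit$config)[c("n_chains", "n_iter", "seed", "penalty")]
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
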