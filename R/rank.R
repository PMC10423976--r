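#' Rank fitted models by AIC
#'
#' Sorts a set of fits of different models to the *same* observations by
#' ascending AIC and attaches the AIC difference to the best model together
#' with the conventional support class: `delta < 2` essentially equivalent
#' ("equivalent"), `2 <= delta < 10` little support ("little"),
#' `delta >= 10` no support ("none").
#'
#' @param fits list of [pheno_fit()] objects fitted to identical observation
#'   sets (checked; a comparability error is raised otherwise).
#' @return a `pheno_ranking` data frame with columns `model`, `k`, `rmse`,
#'   `aic`, `delta_aic`, `support`.
#' @export
rank_models <- function(fits) {
  if (!length(fits)) stop("need at least one fit")
  key <- function(f) paste(f$observed$enclosure, f$observed$year,
                           f$observed$doy, collapse = ";")
  keys <- vapply(fits, key, character(1))
  if (length(unique(keys)) != 1L)
    stop("comparability error: fits were made on different observation sets")
  out <- data.frame(
    model = vapply(fits, `[[`, character(1), "model"),
    k = vapply(fits, `[[`, numeric(1), "k_params"),
    rmse = vapply(fits, `[[`, numeric(1), "rmse"),
    aic = vapply(fits, `[[`, numeric(1), "aic"),
    stringsAsFactors = FALSE)
  out <- out[order(out$aic), , drop = FALSE]
  out$delta_aic <- out$aic - min(out$aic)
  out$support <- cut(out$delta_aic, c(-Inf, 2, 10, Inf),
                     labels = c("equivalent", "little", "none"),
                     right = FALSE)
  rownames(out) <- NULL
  class(out) <- c("pheno_ranking", "data.frame")
  out
}

#' @export
print.pheno_ranking <- function(x, ...) {
  cat("Model ranking (ascending AIC; support classes at delta 2 and 10):\n")
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Compare temperature driver channels along the depth profile
#'
#' Refits one model per requested temperature channel (air and/or soil
#' depths) with an identical configuration and seed, to ask which depth of
#' the temperature profile best explains the observed transitions. Channels
#' absent from the driver series are reported as absent rather than
#' aborting the scan.
#'
#' @param model model abbreviation.
#' @param transitions observation data frame (see [pheno_fit()]).
#' @param drivers list of [driver_series].
#' @param channels character vector of channels, e.g.
#'   `c("air", "0", "5", "10", "20", "30", "40", "50", "100", "200")`.
#' @param config a [fit_config()]; the same seed is used for every channel.
#' @return data frame with one row per channel: `channel`, `aic`, `rmse`,
#'   `status` (`"ok"`/`"absent"`), plus attribute `fits` with the fit objects.
#' @export
compare_driver_depths <- function(model, transitions, drivers,
                                  channels = c("air", "0", "5", "10", "20",
                                               "30", "40", "50", "100", "200"),
                                  config = fit_config()) {
  rows <- list(); fits <- list()
  for (ch in channels) {
    f <- tryCatch(pheno_fit(model, transitions, drivers, temp_channel = ch,
                            config = config),
                  error = function(e) e)
    if (inherits(f, "error")) {
      rows[[ch]] <- data.frame(channel = ch, aic = NA_real_, rmse = NA_real_,
                               status = "absent", stringsAsFactors = FALSE)
    } else {
      fits[[ch]] <- f
      rows[[ch]] <- data.frame(channel = ch, aic = f$aic, rmse = f$rmse,
                               status = "ok", stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "fits") <- fits
  out
}

#' Apply fitted parameters to another site
#'
#' Pure forward evaluation of a fitted (or externally supplied) parameter
#' vector on new observations and drivers: no refitting. Models whose
#' required channels are missing at the new site (e.g. water-table models at
#' sites without water-table data) are skipped with an explicit notice
#' rather than an error.
#'
#' @param fit a [pheno_fit()], or a model abbreviation (then supply `params`).
#' @param transitions observation data frame at the new site.
#' @param drivers list of [driver_series] for the new site.
#' @param params named parameter vector when `fit` is an abbreviation.
#' @param temp_channel temperature channel at the new site.
#' @return list with `model`, `skipped` (logical), `notice` (when skipped),
#'   `predicted`, `rmse`.
#' @export
apply_fitted <- function(fit, transitions, drivers, params = NULL,
                         temp_channel = NULL) {
  if (inherits(fit, "pheno_fit")) {
    model <- fit$model
    params <- fit$par
    if (is.null(temp_channel)) temp_channel <- fit$temp_channel
  } else {
    model <- fit
    if (is.null(params)) stop("supply params when fit is a model name")
    if (is.null(temp_channel)) temp_channel <- "air"
  }
  matched <- .match_drivers(transitions, drivers)
  pred <- tryCatch(predict_phenology(model, params, matched, temp_channel),
                   error = function(e) e)
  if (inherits(pred, "error")) {
    if (grepl("driver error", conditionMessage(pred)))
      return(list(model = model, skipped = TRUE,
                  notice = conditionMessage(pred),
                  predicted = NULL, rmse = NA_real_))
    stop(pred)
  }
  list(model = model, skipped = FALSE, notice = NULL, predicted = pred,
       rmse = cost_rmse(transitions$doy, pred))
}
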