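# Temperature / CO2 sensitivity statistics: mixed-effects models of
# transition dates on the measured warming differential, per-year ordinary
# regressions, and growing-season extension.

.sens_data <- function(transitions, metadata, season, pft) {
  d <- transitions[transitions$season == season & transitions$pft == pft, ,
                   drop = FALSE]
  if (!nrow(d)) stop("no observations for ", pft, " ", season)
  m <- match(d$enclosure, metadata$enclosure)
  if (anyNA(m)) stop("metadata missing enclosure(s): ",
                     paste(unique(d$enclosure[is.na(m)]), collapse = ", "))
  d$dtemp <- metadata$measured_warming[m]
  d$co2 <- as.numeric(metadata$co2_treatment[m] == "elevated")
  d$year <- factor(d$year)
  d
}

.wald_p <- function(fit, term) {
  tt <- summary(fit)$tTable
  if (!term %in% rownames(tt)) return(NA_real_)
  tt[term, "p-value"]
}

#' Mixed-effects temperature/CO2 sensitivity of transition dates
#'
#' Fits `doy ~ dtemp * co2` (measured warming differential in degC; CO2 as a
#' 0/1 treatment indicator) with a random intercept per year, using
#' `nlme::lme`. With `reduce = TRUE` the interaction and then the CO2 main
#' effect are removed when their Wald p-value exceeds `alpha` (maximum
#' likelihood during elimination; the final model is refitted by REML).
#' When all observations share one CO2 level the CO2 terms are omitted from
#' the start. If the mixed model cannot be estimated (e.g. zero residual
#' variance in noise-free data), the fixed effects are estimated by ordinary
#' least squares and the year variance reported as zero.
#'
#' @param transitions observation data frame (`enclosure`, `year`, `pft`,
#'   `season`, `doy`).
#' @param metadata an [enclosure_metadata()] table supplying
#'   `measured_warming` and `co2_treatment` per enclosure.
#' @param season,pft subset selectors.
#' @param reduce perform backward elimination (default `TRUE`); set `FALSE`
#'   to keep the requested structure.
#' @param formula_terms optional explicit fixed-effects structure, one of
#'   `"dtemp"`, `"dtemp+co2"`, `"dtemp*co2"`; overrides `reduce`.
#' @param alpha significance level for elimination, default 0.05.
#' @return object of class `pheno_sensitivity`: coefficient table
#'   (`estimate`, `se`, `t`, `p`), `year_sd`, `resid_sd`, `n`, `formula`,
#'   `method` (`"lme"` or `"ols"`), and the underlying model object.
#' @export
fit_sensitivity_lme <- function(transitions, metadata, season, pft,
                                reduce = TRUE, formula_terms = NULL,
                                alpha = 0.05) {
  d <- .sens_data(transitions, metadata, season, pft)
  if (length(unique(d$year)) < 2) stop("need at least two years")
  if (length(unique(d$dtemp)) < 2)
    stop("rank-deficiency error: a single warming level cannot identify a slope")
  has_co2 <- length(unique(d$co2)) > 1
  if (is.null(formula_terms)) {
    formula_terms <- if (has_co2) "dtemp*co2" else "dtemp"
  } else if (!has_co2 && grepl("co2", formula_terms)) {
    formula_terms <- "dtemp"
  }
  fit_one <- function(terms, method) {
    fml <- as.formula(paste("doy ~", terms))
    tryCatch(nlme::lme(fml, random = ~ 1 | year, data = d, method = method),
             error = function(e) e)
  }
  # Wald p for a term, from the ML mixed fit or, when that fit is not
  # estimable (degenerate variance), from the OLS fixed-effects fit
  term_p <- function(terms, term) {
    f <- fit_one(terms, "ML")
    if (!inherits(f, "error")) return(.wald_p(f, term))
    sm <- summary(lm(as.formula(paste("doy ~", terms)), data = d))$coefficients
    if (term %in% rownames(sm)) sm[term, 4] else NA_real_
  }
  terms <- formula_terms
  if (reduce && has_co2 && terms == "dtemp*co2") {
    p_int <- term_p("dtemp*co2", "dtemp:co2")
    if (is.na(p_int) || p_int >= alpha) {
      terms <- "dtemp+co2"
      p_co2 <- term_p(terms, "co2")
      if (is.na(p_co2) || p_co2 >= alpha) terms <- "dtemp"
    }
  }
  fit <- fit_one(terms, "REML")
  if (inherits(fit, "error")) {
    # degenerate variance structure: fall back to OLS fixed effects
    lmfit <- lm(as.formula(paste("doy ~", terms)), data = d)
    sm <- summary(lmfit)$coefficients
    coefs <- data.frame(term = rownames(sm), estimate = sm[, 1], se = sm[, 2],
                        t = sm[, 3], p = sm[, 4], row.names = NULL)
    out <- list(coefficients = coefs, year_sd = 0,
                resid_sd = summary(lmfit)$sigma, n = nrow(d),
                formula = paste("doy ~", terms), method = "ols",
                model = lmfit, pft = pft, season = season)
  } else {
    tt <- summary(fit)$tTable
    coefs <- data.frame(term = rownames(tt), estimate = tt[, "Value"],
                        se = tt[, "Std.Error"], t = tt[, "t-value"],
                        p = tt[, "p-value"], row.names = NULL)
    vc <- nlme::VarCorr(fit)
    out <- list(coefficients = coefs,
                year_sd = suppressWarnings(as.numeric(vc["(Intercept)", "StdDev"])),
                resid_sd = fit$sigma, n = nrow(d),
                formula = paste("doy ~", terms), method = "lme",
                model = fit, pft = pft, season = season)
  }
  class(out) <- "pheno_sensitivity"
  out
}

#' @export
print.pheno_sensitivity <- function(x, ...) {
  cat(sprintf("Sensitivity of %s %s transition dates (%s, n = %d)\n",
              x$pft, x$season, x$formula, x$n))
  print(x$coefficients, row.names = FALSE, digits = 4)
  cat(sprintf("Random year SD %.2f d; residual SD %.2f d [%s]\n",
              x$year_sd, x$resid_sd, x$method))
  invisible(x)
}

#' @export
coef.pheno_sensitivity <- function(object, ...) {
  setNames(object$coefficients$estimate, object$coefficients$term)
}

#' Per-year temperature sensitivity
#'
#' Ordinary regression slope of transition DOY on the measured warming
#' differential within each year; years with fewer than three enclosures are
#' flagged undefined (`NA` slope).
#'
#' @inheritParams fit_sensitivity_lme
#' @return data frame with `year`, `slope` (days per degC), `se`, `n`.
#' @export
per_year_sensitivity <- function(transitions, metadata, season, pft) {
  d <- .sens_data(transitions, metadata, season, pft)
  out <- lapply(split(d, d$year), function(dy) {
    if (nrow(dy) < 3 || length(unique(dy$dtemp)) < 2)
      return(data.frame(year = as.integer(as.character(dy$year[1])),
                        slope = NA_real_, se = NA_real_, n = nrow(dy)))
    f <- summary(lm(doy ~ dtemp, data = dy))$coefficients
    data.frame(year = as.integer(as.character(dy$year[1])),
               slope = f["dtemp", 1], se = f["dtemp", 2], n = nrow(dy))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Growing-season extension per degree of warming
#'
#' The change in growing-season length per degC: the autumn slope minus the
#' spring slope, so a spring advance (negative slope) counts positively
#' toward extension. Accepts two [fit_sensitivity_lme()] records (their
#' `dtemp` coefficients are used), two [per_year_sensitivity()] tables
#' (matched by year; missing pairs are an error), or two plain numbers.
#'
#' @param spring,autumn the spring and autumn sensitivities.
#' @return extension in days per degC (a vector per year for table input).
#' @export
season_extension <- function(spring, autumn) {
  slope_of <- function(x) {
    if (inherits(x, "pheno_sensitivity")) return(coef(x)[["dtemp"]])
    x
  }
  if (is.data.frame(spring) && is.data.frame(autumn)) {
    missing_pairs <- c(setdiff(spring$year, autumn$year),
                       setdiff(autumn$year, spring$year))
    if (length(missing_pairs))
      stop("mismatched year coverage: ", paste(missing_pairs, collapse = ", "))
    m <- match(spring$year, autumn$year)
    return(setNames(autumn$slope[m] - spring$slope, spring$year))
  }
  slope_of(autumn) - slope_of(spring)
}
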