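# Statistical models of color-morph expression. Three families are fit and
# compared within family by AIC (deviance + 2 * effective df; exact for
# Bernoulli responses, where the saturated log-likelihood is zero):
#   * cyclic-spline binomial GAMs of week-of-year and latitude (phenology),
#   * binomial GLMs of hourly temperature and breeding season (thermal
#     hypothesis), with the interaction parameterized as one temperature
#     slope per season so each slope has its own SE,
#   * OLS of organism greenness on background greenness (crypsis check).

#' Assign the breeding/non-breeding season of a date
#'
#' The breeding window is fixed at 1 April through 30 September inclusive
#' (breeding phenology shifts little across the latitudes considered);
#' all other dates are non-breeding.
#'
#' @param date a `Date` vector (or coercible).
#' @return character vector, `"breeding"` or `"nonbreeding"`.
#' @export
assign_season <- function(date) {
  m <- as.POSIXlt(as.Date(date))$mon + 1L
  ifelse(m >= 4L & m <= 9L, "breeding", "nonbreeding")
}

#' Continuous week-of-year on a 52-week cycle
#'
#' `week = (day_of_year - 1) / 7`, with day 366 mapped to 365 and the
#' result wrapped modulo 52 so day 365 (week 52.0) closes the cycle at 0.
#'
#' @param date a `Date` vector (or coercible).
#' @return numeric in `[0, 52)`.
#' @export
week_of_year <- function(date) {
  doy <- pmin(as.POSIXlt(as.Date(date))$yday + 1L, 365L)
  ((doy - 1) / 7) %% 52
}

SEASON_LEVELS <- c("nonbreeding", "breeding")

prepare_model_records <- function(records) {
  stopifnot(is.data.frame(records))
  if (!"label" %in% names(records)) stop("records need a 'label' column",
                                         call. = FALSE)
  bad <- !records$label %in% c("green", "brown")
  if (any(bad)) {
    stop("records contain labels other than green/brown; ",
         "exclude 'unclear' rows before modeling", call. = FALSE)
  }
  records$y <- as.integer(records$label == "green") # green = 1
  if (!"season" %in% names(records) && "date" %in% names(records)) {
    records$season <- assign_season(records$date)
  }
  if ("season" %in% names(records)) {
    records$season <- factor(records$season, levels = SEASON_LEVELS)
  }
  if (!"week" %in% names(records) && "date" %in% names(records)) {
    records$week <- week_of_year(records$date)
  }
  records
}

new_anole_fit <- function(model_name, fit, effective_df, extra = list()) {
  dev <- stats::deviance(fit)
  null_dev <- if (!is.null(fit$null.deviance)) fit$null.deviance else NA_real_
  n <- stats::nobs(fit)
  sm <- summary(fit)
  if (inherits(fit, "gam")) {
    coefs <- fit$coefficients
    ses <- sqrt(pmax(diag(fit$Vp), 0))
  } else {
    coefs <- stats::coef(fit)
    ses <- sqrt(diag(stats::vcov(fit)))
  }
  structure(c(list(
    model_name = model_name,
    fit = fit,
    coefficients = coefs,
    se = ses,
    deviance = dev,
    null_deviance = null_dev,
    effective_df = effective_df,
    aic = dev + 2 * effective_df,
    deviance_explained = (null_dev - dev) / null_dev,
    adj_pseudo_r2 = 1 - (dev / (n - effective_df)) / (null_dev / (n - 1)),
    n = n,
    y = fit$y
  ), extra), class = "anole_fit")
}

#' @export
print.anole_fit <- function(x, ...) {
  cat(sprintf("<anole_fit '%s': n = %d, deviance = %.2f, edf = %.2f, AIC = %.2f,\n  deviance explained = %.2f%% (adj. pseudo-R2 %.3f, approximate)>\n",
              x$model_name, x$n, x$deviance, x$effective_df, x$aic,
              100 * x$deviance_explained, x$adj_pseudo_r2))
  invisible(x)
}

#' @export
predict.anole_fit <- function(object, newdata, ...) {
  predict_with_ci(object, newdata, ...)
}

check_separation <- function(fit) {
  co <- stats::coef(fit)
  big <- abs(co) > 15
  if (any(big, na.rm = TRUE)) {
    stop("apparent complete separation (unstable term(s): ",
         paste(names(co)[which(big)], collapse = ", "), ")", call. = FALSE)
  }
}

#' Binomial logistic regression of color morph on temperature and season
#'
#' Fits green(1)/brown(0) against hourly temperature by IRLS, in one of
#' three designs: temperature only; temperature plus a season main effect;
#' or the interaction variant with a separate temperature slope for each
#' season (`y ~ season + season:hourly_temp`), which is the same model as
#' `hourly_temp * season` but reports per-season slopes directly.
#'
#' @param records data frame with `label` (`green`/`brown`), `hourly_temp`,
#'   and (for the season variants) `season` or `date`.
#' @param formula_variant one of `"temp_only"`, `"temp_plus_season"`,
#'   `"temp_by_season_interaction"`.
#' @return an `anole_fit`; the interaction variant also carries
#'   `season_slopes`, a per-season table of slope, SE, z and p.
#' @export
fit_logistic <- function(records,
                         formula_variant = c("temp_only", "temp_plus_season",
                                             "temp_by_season_interaction")) {
  formula_variant <- match.arg(formula_variant)
  d <- prepare_model_records(records)
  if (length(unique(d$y)) < 2L) {
    stop("both labels must be present to fit a logistic model", call. = FALSE)
  }
  if (formula_variant != "temp_only") {
    if (!"season" %in% names(d)) stop("records need 'season' or 'date'",
                                      call. = FALSE)
    if (any(table(d$season) < 10L)) {
      stop("need at least 10 records per season level", call. = FALSE)
    }
  }
  f <- switch(formula_variant,
              temp_only = y ~ hourly_temp,
              temp_plus_season = y ~ hourly_temp + season,
              temp_by_season_interaction = y ~ season + season:hourly_temp)
  fit <- stats::glm(f, family = stats::binomial(), data = d)
  check_separation(fit)
  extra <- list(variant = formula_variant)
  if (formula_variant == "temp_by_season_interaction") {
    co <- stats::coef(fit)
    se <- sqrt(diag(stats::vcov(fit)))
    nm <- paste0("season", SEASON_LEVELS, ":hourly_temp")
    sl <- data.frame(season = SEASON_LEVELS, slope = co[nm], se = se[nm])
    sl$z <- sl$slope / sl$se
    sl$p_value <- 2 * stats::pnorm(-abs(sl$z))
    rownames(sl) <- NULL
    extra$season_slopes <- sl
  }
  new_anole_fit(formula_variant, fit, length(stats::coef(fit)), extra)
}

#' Cyclic-spline binomial GAM of color morph phenology
#'
#' Penalized binomial additive model of green(1)/brown(0) on week of year
#' (cyclic cubic regression spline, period 52) and latitude (low-rank
#' thin-plate smooth with basis dimension `k_lat = 3`). The interaction
#' variant uses a tensor product of the two marginal bases. Smoothing
#' parameters are chosen by GCV; effective degrees of freedom are the
#' penalized-hat-matrix trace, and AIC is `deviance + 2 * edf`.
#'
#' @param records data frame with `label`, `latitude`, and `week` or `date`.
#' @param variant `"week_only"`, `"week_plus_lat"`, or
#'   `"week_by_lat_interaction"`.
#' @param k_week basis dimension of the cyclic week spline (default 6;
#'   knots evenly spaced on `[0, 52]`).
#' @param k_lat basis dimension of the latitude smooth (default 3).
#' @return an `anole_fit` whose predictions are periodic in `week`.
#' @export
fit_cyclic_gam <- function(records,
                           variant = c("week_only", "week_plus_lat",
                                       "week_by_lat_interaction"),
                           k_week = 6, k_lat = 3) {
  variant <- match.arg(variant)
  d <- prepare_model_records(records)
  if (length(unique(d$y)) < 2L) {
    stop("both labels must be present to fit a GAM", call. = FALSE)
  }
  if (diff(range(d$week)) < 45) {
    warning("week values do not cover the annual cycle; ",
            "the cyclic constraint is poorly informed")
  }
  f <- switch(variant,
              week_only = y ~ s(week, bs = "cc", k = k_week),
              week_plus_lat = y ~ s(week, bs = "cc", k = k_week) +
                s(latitude, bs = "tp", k = k_lat),
              week_by_lat_interaction =
                y ~ te(week, latitude, bs = c("cc", "tp"),
                       k = c(k_week, k_lat)))
  fit <- mgcv::gam(f, family = stats::binomial(), data = d,
                   knots = list(week = seq(0, 52, length.out = k_week)),
                   method = "GCV.Cp")
  new_anole_fit(variant, fit, sum(fit$edf),
                list(variant = variant, cyclic_var = "week",
                     cyclic_period = 52))
}

#' Compare fitted models by AIC
#'
#' @param fits a list of `anole_fit` objects fit to the same records.
#' @return a list with the AIC `table` (model, deviance, edf, aic), the
#'   `best` model name (minimum AIC; ties broken toward fewer effective
#'   df), `delta_aic` (best minus runner-up, hence `<= 0`), and `fits`.
#' @export
aic_compare <- function(fits) {
  stopifnot(length(fits) >= 2L,
            all(vapply(fits, inherits, logical(1), "anole_fit")))
  y0 <- fits[[1]]$y
  same <- vapply(fits, function(f) {
    length(f$y) == length(y0) && all(f$y == y0)
  }, logical(1))
  if (!all(same)) {
    stop("fits were made on differing record sets; AICs are not comparable",
         call. = FALSE)
  }
  tab <- data.frame(
    model = vapply(fits, `[[`, character(1), "model_name"),
    deviance = vapply(fits, `[[`, numeric(1), "deviance"),
    edf = vapply(fits, `[[`, numeric(1), "effective_df"),
    aic = vapply(fits, `[[`, numeric(1), "aic"))
  ord <- order(tab$aic, tab$edf)
  best <- ord[1L]
  list(table = tab,
       best = tab$model[best],
       delta_aic = tab$aic[best] - tab$aic[ord[2L]],
       fits = fits)
}

#' Back-transformed predictions with confidence intervals
#'
#' Evaluates the linear predictor and its standard error on the logit
#' scale, forms `eta +/- z * se` at the requested level, and inverse-logit
#' transforms all three, so `lower <= probability <= upper` always holds.
#' For cyclic GAM fits the `week` covariate is wrapped modulo 52 first,
#' making predictions invariant to adding whole cycles.
#'
#' @param fit an `anole_fit`.
#' @param newdata data frame of covariates.
#' @param level confidence level (default 0.95).
#' @return a data frame with `probability`, `lower`, `upper`,
#'   `linear_predictor`, `se`.
#' @export
predict_with_ci <- function(fit, newdata, level = 0.95) {
  stopifnot(inherits(fit, "anole_fit"), is.data.frame(newdata))
  needed <- setdiff(intersect(all.vars(stats::formula(fit$fit)),
                              names(fit$fit$model)), c("y", "label"))
  missing_vars <- setdiff(needed, names(newdata))
  if (length(missing_vars)) {
    stop("newdata lacks covariate(s): ", paste(missing_vars, collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(fit$cyclic_var) && fit$cyclic_var %in% names(newdata)) {
    newdata[[fit$cyclic_var]] <- newdata[[fit$cyclic_var]] %% fit$cyclic_period
  }
  for (v in needed) {
    if (identical(v, fit$cyclic_var)) next # periodic: any value is in range
    if (is.numeric(newdata[[v]]) && !is.null(fit$fit$model[[v]])) {
      r <- range(fit$fit$model[[v]])
      if (any(newdata[[v]] < r[1] | newdata[[v]] > r[2])) {
        warning("covariate '", v, "' outside the fitted range")
      }
    }
  }
  pr <- stats::predict(fit$fit, newdata = newdata, type = "link",
                       se.fit = TRUE)
  z <- stats::qnorm((1 + level) / 2)
  eta <- as.numeric(pr$fit)
  se <- as.numeric(pr$se.fit)
  data.frame(probability = stats::plogis(eta),
             lower = stats::plogis(eta - z * se),
             upper = stats::plogis(eta + z * se),
             linear_predictor = eta,
             se = se)
}

#' Background-matching regression with temperature-confounder check
#'
#' OLS of organism greenness on background greenness (both as G/(R+G+B)
#' indices). A strong positive slope would indicate background matching.
#' When `hourly_temp` is available the Pearson correlation of background
#' greenness with temperature and the slope p-value of the regression of
#' temperature on background greenness are reported alongside, to check
#' whether background color could confound the temperature models.
#'
#' @param records data frame with `greenness`, `bg_greenness`, optionally
#'   `hourly_temp`.
#' @return a list: `slope`, `intercept`, `r_squared`, `p_value`, `n`, and
#'   `confounder` (`cor_bg_temp`, `p_value_temp_on_bg`, or `NA` without
#'   temperatures).
#' @export
fit_background_lm <- function(records) {
  d <- records[is.finite(records$greenness) & is.finite(records$bg_greenness),
               , drop = FALSE]
  if (nrow(d) < 3L) stop("need at least 3 records with finite indices",
                         call. = FALSE)
  if (stats::var(d$bg_greenness) == 0) {
    stop("background greenness has zero variance", call. = FALSE)
  }
  fit <- stats::lm(greenness ~ bg_greenness, data = d)
  sm <- summary(fit)
  conf <- list(cor_bg_temp = NA_real_, p_value_temp_on_bg = NA_real_)
  if ("hourly_temp" %in% names(d) && any(is.finite(d$hourly_temp))) {
    dd <- d[is.finite(d$hourly_temp), , drop = FALSE]
    conf$cor_bg_temp <- stats::cor(dd$bg_greenness, dd$hourly_temp)
    rev_fit <- summary(stats::lm(hourly_temp ~ bg_greenness, data = dd))
    conf$p_value_temp_on_bg <- rev_fit$coefficients["bg_greenness", 4]
  }
  list(slope = unname(stats::coef(fit)["bg_greenness"]),
       intercept = unname(stats::coef(fit)["(Intercept)"]),
       r_squared = sm$r.squared,
       p_value = sm$coefficients["bg_greenness", 4],
       n = nrow(d),
       confounder = conf)
}
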