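#' Specify one mortality regression
#'
#' Describes a single quasi-Poisson regression: the cause-specific
#' outcome, the exposure term(s) as lag-window means, the natural-spline
#' smoother degrees of freedom for time trend, temperature and RH, the
#' weather lag convention, the indicator covariates, and the analysis
#' stratum. The influenza indicator is included only for total and
#' cardiovascular mortality by default (it is derived from respiratory
#' mortality).
#'
#' @param cause one of `"total"`, `"cvd"`, `"resp"`.
#' @param pollutant exposure column, e.g. `"o3_8h"`.
#' @param lags lag set for the exposure window (default lag 1--2 mean).
#' @param copollutant optional second pollutant entering linearly.
#' @param copollutant_lags lag set for the co-pollutant.
#' @param time_df_per_year df/year for the time-trend spline.
#' @param time_df absolute total time df; overrides the per-year rule
#'   (used in the stratified analysis: 2 df peak, 6 df nonpeak).
#' @param temp_df,rh_df spline df for temperature and RH smooths.
#' @param weather_lag `"lag1"` single-day lag 1 (default), `"lag0"`,
#'   `"lag23"` (mean of lags 2--3), or `"lag46"` (mean of lags 4--6).
#' @param use_year,use_dow,use_holiday,use_flu indicator covariates
#'   on/off.
#' @param include_temp,include_rh weather smooths on/off.
#' @param stratum `"all"`, `"peak"` (Sep--Nov) or `"nonpeak"` (Dec--Aug).
#' @return object of class `"model_spec"`.
#' @export
model_spec <- function(cause = "total", pollutant = "o3_8h", lags = c(1, 2),
                       copollutant = NULL, copollutant_lags = c(1, 2),
                       time_df_per_year = 7, time_df = NULL,
                       temp_df = 3, rh_df = 3,
                       weather_lag = c("lag1", "lag0", "lag23", "lag46"),
                       use_year = TRUE, use_dow = TRUE, use_holiday = TRUE,
                       use_flu = cause %in% c("total", "cvd"),
                       include_temp = TRUE, include_rh = TRUE,
                       stratum = c("all", "peak", "nonpeak")) {
  cause <- match.arg(cause, c("total", "cvd", "resp"))
  weather_lag <- match.arg(weather_lag)
  stratum <- match.arg(stratum)
  structure(list(cause = cause, pollutant = pollutant, lags = lags,
                 copollutant = copollutant, copollutant_lags = copollutant_lags,
                 time_df_per_year = time_df_per_year, time_df = time_df,
                 temp_df = temp_df, rh_df = rh_df, weather_lag = weather_lag,
                 use_year = use_year, use_dow = use_dow,
                 use_holiday = use_holiday, use_flu = use_flu,
                 include_temp = include_temp, include_rh = include_rh,
                 stratum = stratum), class = "model_spec")
}

weather_lag_set <- function(weather_lag) {
  switch(weather_lag, lag0 = 0L, lag1 = 1L, lag23 = c(2L, 3L),
         lag46 = c(4L, 5L, 6L))
}

#' Build the regression design matrix for a model specification
#'
#' Assembles the covariate matrix from a prepared daily series: exposure
#' lag-window mean(s), natural-spline smooths of the time trend (day
#' index) and lagged temperature/RH, and year/DOW/holiday/influenza
#' indicators (one-hot, first level as reference). Lag windows are
#' computed on the full calendar before any stratum subsetting, so
#' cross-boundary lags use true calendar neighbours; rows with any
#' missing covariate are dropped afterwards (complete-case; no
#' imputation). Indicator columns that are constant on the analysis rows
#' are dropped and recorded.
#'
#' @param series prepared daily series (see [prepare_series()]).
#' @param spec a [model_spec()].
#' @param holidays optional Date vector; used if the series lacks a
#'   `holiday` column.
#' @param include_dates optional Date vector restricting the analysis
#'   rows (used by percentile-exclusion sensitivity analyses).
#' @return list: `X` (design matrix with intercept), `y` (counts),
#'   `dates`, `exposure_col` (and `copollutant_col`), `n_dropped`,
#'   `dropped_constant` (names of removed constant indicators).
#' @export
build_design <- function(series, spec, holidays = NULL, include_dates = NULL) {
  stopifnot(inherits(spec, "model_spec"))
  check_calendar(series)
  ycol <- paste0("deaths_", spec$cause)
  if (!ycol %in% names(series))
    stop(sprintf("outcome column '%s' not found", ycol))
  if (!spec$pollutant %in% names(series))
    stop(sprintf("exposure column '%s' not found", spec$pollutant))
  if (all(is.na(series[[spec$pollutant]])))
    stop(sprintf("exposure column '%s' is entirely missing", spec$pollutant))
  dates <- as.Date(series$date)

  cov <- data.frame(row.names = seq_len(nrow(series)))
  exposure_col <- sprintf("%s_lag%s", spec$pollutant,
                          paste(spec$lags, collapse = ""))
  cov[[exposure_col]] <- lag_window_mean(series, spec$pollutant, spec$lags)
  copollutant_col <- NULL
  if (!is.null(spec$copollutant)) {
    copollutant_col <- sprintf("%s_lag%s", spec$copollutant,
                               paste(spec$copollutant_lags, collapse = ""))
    cov[[copollutant_col]] <- lag_window_mean(series, spec$copollutant,
                                              spec$copollutant_lags)
  }
  wl <- weather_lag_set(spec$weather_lag)
  if (spec$include_temp) cov$temp_l <- lag_window_mean(series, "temp", wl)
  if (spec$include_rh) cov$rh_l <- lag_window_mean(series, "rh", wl)

  if (spec$use_flu) {
    flu <- if ("flu" %in% names(series)) series$flu
           else influenza_indicator(series$deaths_resp)
    cov$flu <- flu
  }
  if (spec$use_holiday) {
    hol <- if ("holiday" %in% names(series)) series$holiday
           else if (!is.null(holidays)) as.integer(dates %in% as.Date(holidays))
           else NULL
    if (!is.null(hol)) cov$holiday <- hol
  }

  keep <- rep(TRUE, nrow(series))
  if (spec$stratum != "all") {
    period <- if ("period" %in% names(series)) series$period
              else label_periods(dates)
    keep <- keep & (period == spec$stratum)
  }
  if (!is.null(include_dates)) keep <- keep & (dates %in% as.Date(include_dates))

  y_all <- series[[ycol]]
  cc <- keep & stats::complete.cases(cov) & !is.na(y_all)
  n_dropped <- sum(keep) - sum(cc)
  if (sum(cc) < 10) stop("fewer than 10 complete analysis rows")
  dsub <- dates[cc]
  csub <- cov[cc, , drop = FALSE]
  y <- y_all[cc]
  if (any(y != round(y))) stop("death counts must be integers")

  parts <- list("(Intercept)" = rep(1, sum(cc)))
  for (nm in names(csub)) parts[[nm]] <- csub[[nm]]

  # time trend: day index of the analysis stratum's own dates
  tindex <- as.numeric(dsub - min(dates)) + 1
  time_df <- if (!is.null(spec$time_df)) spec$time_df
             else max(1L, floor(spec$time_df_per_year *
                                  (as.numeric(max(dates) - min(dates)) + 1) / 365.25 + 0.5))
  tb <- ns_basis(tindex, df = time_df)
  tm <- tb$basis; colnames(tm) <- paste0("time_", colnames(tm))
  parts$time <- tm

  if (spec$include_temp) {
    bb <- ns_basis(csub$temp_l, df = spec$temp_df)
    m <- bb$basis; colnames(m) <- paste0("temp_", colnames(m))
    parts$temp_l <- NULL; parts$temp <- m
  }
  if (spec$include_rh) {
    bb <- ns_basis(csub$rh_l, df = spec$rh_df)
    m <- bb$basis; colnames(m) <- paste0("rh_", colnames(m))
    parts$rh_l <- NULL; parts$rh <- m
  }
  if (spec$use_year) {
    yr <- factor(format(dsub, "%Y"))
    if (nlevels(yr) > 1) {
      m <- stats::model.matrix(~yr)[, -1, drop = FALSE]
      colnames(m) <- sub("^yr", "year_", colnames(m))
      parts$year <- m
    }
  }
  if (spec$use_dow) {
    dw <- factor(format(dsub, "%u"), levels = as.character(1:7))
    dw <- droplevels(dw)
    if (nlevels(dw) > 1) {
      m <- stats::model.matrix(~dw)[, -1, drop = FALSE]
      colnames(m) <- sub("^dw", "dow_", colnames(m))
      parts$dow <- m
    }
  }

  X <- do.call(cbind, lapply(names(parts), function(nm) {
    p <- parts[[nm]]
    if (is.null(dim(p))) { p <- matrix(p, ncol = 1); colnames(p) <- nm }
    p
  }))
  # drop constant indicator columns (e.g. no holidays inside a stratum)
  const <- apply(X, 2, function(col) length(unique(col)) == 1L)
  const["(Intercept)"] <- FALSE
  dropped_constant <- colnames(X)[const]
  X <- X[, !const, drop = FALSE]

  list(X = X, y = y, dates = dsub, exposure_col = exposure_col,
       copollutant_col = copollutant_col, n_dropped = n_dropped,
       dropped_constant = dropped_constant, time_df = time_df)
}

#' Excess risk from a log-relative-risk coefficient
#'
#' Converts a log-relative-risk per ug/m3 and its standard error into the
#' percent excess risk at a stated increment,
#' \eqn{ER = (e^{\beta\Delta} - 1) \times 100}, with the 95% CI obtained
#' by transforming the endpoints \eqn{\beta \pm 1.96\,SE}.
#'
#' @param beta log-relative-risk per ug/m3.
#' @param se standard error of `beta`.
#' @param delta exposure increment (ug/m3), default 10.
#' @return named numeric: `er`, `lo`, `hi` (percent).
#' @export
excess_risk <- function(beta, se, delta = 10) {
  beta <- unname(beta); se <- unname(se)
  c(er = (exp(beta * delta) - 1) * 100,
    lo = (exp((beta - 1.96 * se) * delta) - 1) * 100,
    hi = (exp((beta + 1.96 * se) * delta) - 1) * 100)
}

#' Recover a coefficient and SE from a published excess risk with CI
#'
#' Inverse of [excess_risk()], used to consume printed tables:
#' \eqn{\beta = \ln(1 + ER/100)/\Delta} and
#' \eqn{SE = [\ln(1 + hi/100) - \ln(1 + lo/100)]/(2 \times 1.96 \Delta)}.
#'
#' @param er_percent excess risk in percent.
#' @param lo,hi 95% CI endpoints in percent (`lo < hi`).
#' @param delta increment the ER refers to (ug/m3).
#' @return named numeric: `beta`, `se`.
#' @export
beta_from_er <- function(er_percent, lo, hi, delta = 10) {
  er_percent <- unname(er_percent); lo <- unname(lo); hi <- unname(hi)
  if (any(lo > hi)) stop("malformed CI: lower endpoint exceeds upper endpoint")
  c(beta = log(1 + er_percent / 100) / delta,
    se = (log(1 + hi / 100) - log(1 + lo / 100)) / (2 * 1.96 * delta))
}

new_effect_estimate <- function(fit, design, spec, scope, delta = 10) {
  b <- fit$coefficients[design$exposure_col]
  s <- fit$se[design$exposure_col]
  er <- excess_risk(b, s, delta)
  structure(list(pollutant = spec$pollutant, cause = spec$cause,
                 scope = scope, stratum = spec$stratum,
                 copollutant = spec$copollutant,
                 beta = unname(b), se = unname(s), delta = delta,
                 er = unname(er["er"]), lo = unname(er["lo"]),
                 hi = unname(er["hi"]),
                 z = unname(b / s), phi = fit$phi, n_obs = fit$n_obs,
                 time_df = design$time_df, spec = spec),
            class = "effect_estimate")
}

#' @export
print.effect_estimate <- function(x, ...) {
  adj <- if (is.null(x$copollutant)) "single-pollutant"
         else paste("adjusted for", x$copollutant)
  cat(sprintf("%s ~ %s (%s, %s, %s): ER %.2f%% (%.2f, %.2f) per %g ug/m3 [n=%d, phi=%.2f]\n",
              x$cause, x$pollutant, x$scope, x$stratum, adj,
              x$er, x$lo, x$hi, x$delta, x$n_obs, x$phi))
  invisible(x)
}

#' @export
as.data.frame.effect_estimate <- function(x, ...) {
  data.frame(pollutant = x$pollutant, cause = x$cause, scope = x$scope,
             stratum = x$stratum,
             copollutant = if (is.null(x$copollutant)) NA_character_ else x$copollutant,
             beta = x$beta, se = x$se, delta = x$delta,
             er = x$er, lo = x$lo, hi = x$hi, z = x$z,
             phi = x$phi, n_obs = x$n_obs, stringsAsFactors = FALSE)
}

#' Single-pollutant excess-risk model
#'
#' Fits the standard single-pollutant quasi-Poisson model (time trend,
#' temperature, RH smooths; year, DOW, holiday and -- for total and
#' cardiovascular mortality -- influenza indicators) and returns the
#' excess risk per `delta` ug/m3 of the lag-window mean exposure. Lag
#' windows 0..6 and the 2-day means `{0,1}` and `{1,2}` are supported via
#' `lags`.
#'
#' @param series prepared daily series.
#' @param pollutant exposure column.
#' @param cause outcome cause.
#' @param lags exposure lag set (default lag 1--2 mean).
#' @param spec optional [model_spec()] overriding the defaults.
#' @param holidays optional holiday calendar.
#' @param delta reporting increment (ug/m3).
#' @param scope label recorded on the estimate (city name or
#'   `"merged"`).
#' @return an `"effect_estimate"`.
#' @export
run_single_pollutant <- function(series, pollutant = "o3_8h",
                                 cause = "total", lags = c(1, 2),
                                 spec = NULL, holidays = NULL, delta = 10,
                                 scope = "city") {
  if (is.null(spec))
    spec <- model_spec(cause = cause, pollutant = pollutant, lags = lags)
  else { spec$pollutant <- pollutant; spec$cause <- cause; spec$lags <- lags
         spec["copollutant"] <- list(NULL) }
  d <- build_design(series, spec, holidays = holidays)
  fit <- fit_irls(d$X, d$y)
  new_effect_estimate(fit, d, spec, scope, delta)
}

#' Two-pollutant excess-risk model
#'
#' Adds the co-pollutant's lag-window mean linearly and reports the index
#' pollutant's estimate. Refused when the Pearson correlation between the
#' two lag-window means (pairwise complete, on the analysis window)
#' reaches 0.6 in absolute value, to avoid collinear two-pollutant
#' models.
#'
#' @inheritParams run_single_pollutant
#' @param copollutant adjusting pollutant column.
#' @param copollutant_lags its lag set.
#' @param max_correlation refusal threshold (default 0.6).
#' @return an `"effect_estimate"` for the index pollutant.
#' @export
run_two_pollutant <- function(series, pollutant, copollutant,
                              cause = "total", lags = c(1, 2),
                              copollutant_lags = c(1, 2), spec = NULL,
                              holidays = NULL, delta = 10, scope = "city",
                              max_correlation = 0.6) {
  if (is.null(spec)) spec <- model_spec(cause = cause, pollutant = pollutant,
                                        lags = lags)
  spec$pollutant <- pollutant; spec$cause <- cause; spec$lags <- lags
  spec$copollutant <- copollutant; spec$copollutant_lags <- copollutant_lags
  tmp <- series
  tmp$.x1 <- lag_window_mean(series, pollutant, lags)
  tmp$.x2 <- lag_window_mean(series, copollutant, copollutant_lags)
  r <- pearson_corr(tmp, ".x1", ".x2")
  if (!is.na(r) && abs(r) >= max_correlation)
    stop(sprintf("two-pollutant model refused: Pearson correlation between %s and %s lag-window means is %.2f (|r| must be < %.1f)",
                 pollutant, copollutant, r, max_correlation))
  d <- build_design(series, spec, holidays = holidays)
  fit <- fit_irls(d$X, d$y)
  new_effect_estimate(fit, d, spec, scope, delta)
}

#' Normal z-test for a difference between two stratum estimates
#'
#' \eqn{z = (\beta_{np} - \beta_p)/\sqrt{SE_p^2 + SE_{np}^2}}, two-sided
#' normal p-value, assuming independent strata (disjoint days).
#'
#' @param beta_peak,se_peak peak-period coefficient and SE.
#' @param beta_nonpeak,se_nonpeak nonpeak-period coefficient and SE.
#' @return named numeric: `z`, `p`.
#' @export
stratum_difference <- function(beta_peak, se_peak, beta_nonpeak, se_nonpeak) {
  beta_peak <- unname(beta_peak); beta_nonpeak <- unname(beta_nonpeak)
  z <- (beta_nonpeak - beta_peak) / sqrt(unname(se_peak)^2 + unname(se_nonpeak)^2)
  c(z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Stratified ozone analysis (peak vs nonpeak period)
#'
#' Fits separate models on the September--November (peak) and
#' December--August (nonpeak) days, with 2-df and 6-df time-trend splines
#' respectively (per-stratum bases on each stratum's own dates), other
#' covariates unchanged, and optional PM10 adjustment. Exposure lag
#' windows are computed on the full calendar before subsetting so
#' cross-boundary lags use true calendar neighbours. Returns the two
#' estimates and the z-based difference test.
#'
#' @param series prepared daily series (city-merged in the standard
#'   analysis).
#' @param cause outcome cause.
#' @param adjust_pm10 add the PM10 lag 1--2 mean.
#' @param peak_df,nonpeak_df time-trend df per stratum.
#' @param holidays,delta,scope as in [run_single_pollutant()].
#' @return list with `peak`, `nonpeak` (effect estimates) and
#'   `difference` (`z`, `p`).
#' @export
run_stratified_o3 <- function(series, cause = "total", adjust_pm10 = TRUE,
                              peak_df = 2, nonpeak_df = 6, holidays = NULL,
                              delta = 10, scope = "merged") {
  one <- function(stratum, df) {
    sp <- model_spec(cause = cause, pollutant = "o3_8h", lags = c(1, 2),
                     copollutant = if (adjust_pm10) "pm10" else NULL,
                     time_df = df, stratum = stratum)
    d <- build_design(series, sp, holidays = holidays)
    new_effect_estimate(fit_irls(d$X, d$y), d, sp, scope, delta)
  }
  pk <- one("peak", peak_df)
  np <- one("nonpeak", nonpeak_df)
  list(peak = pk, nonpeak = np,
       difference = stratum_difference(pk$beta, pk$se, np$beta, np$se))
}

# Nearest integer with halves away from zero, floored at 1: the rule for
# scaling spline df by +/-25% (6 x 0.75 -> 5).
scale_df <- function(df, factor) max(1L, as.integer(floor(df * factor + 0.5)))

#' Sensitivity analyses around a base model
#'
#' Re-estimates the base single-pollutant model under the ten standard
#' perturbations: dropping each of the temperature, RH, influenza and
#' holiday covariates; scaling the time and meteorological spline df by
#' 0.75 and 1.25 (nearest integer, minimum 1); lagging temperature by
#' 2--3 or 4--6 days; and excluding days with exposure above the 95th or
#' below the 5th percentile of its observed daily distribution.
#'
#' @param series prepared daily series.
#' @param spec base [model_spec()]; defaults to the standard lag 1--2
#'   ozone/total model.
#' @param holidays,delta as in [run_single_pollutant()].
#' @return data frame with one row per perturbation (`perturbation`,
#'   `er`, `lo`, `hi`, `beta`, `se`, `n_obs`, `pct_change_beta`); the base
#'   estimate is attached as attribute `"base"`.
#' @export
sensitivity_suite <- function(series, spec = model_spec(), holidays = NULL,
                              delta = 10) {
  base_d <- build_design(series, spec, holidays = holidays)
  base_fit <- fit_irls(base_d$X, base_d$y)
  base_est <- new_effect_estimate(base_fit, base_d, spec, "sensitivity", delta)
  base_time_df <- base_d$time_df

  x <- series[[spec$pollutant]]
  q <- stats::quantile(x, c(0.05, 0.95), na.rm = TRUE, type = 7)
  dates <- as.Date(series$date)
  keep_hi <- dates[is.na(x) | x <= q[2]]
  keep_lo <- dates[is.na(x) | x >= q[1]]

  perturb <- list(
    drop_temperature = function(sp) { sp$include_temp <- FALSE; list(spec = sp) },
    drop_rh = function(sp) { sp$include_rh <- FALSE; list(spec = sp) },
    drop_influenza = function(sp) { sp$use_flu <- FALSE; list(spec = sp) },
    drop_holiday = function(sp) { sp$use_holiday <- FALSE; list(spec = sp) },
    df_x0.75 = function(sp) {
      sp$time_df <- scale_df(base_time_df, 0.75)
      sp$temp_df <- scale_df(sp$temp_df, 0.75)
      sp$rh_df <- scale_df(sp$rh_df, 0.75)
      list(spec = sp)
    },
    df_x1.25 = function(sp) {
      sp$time_df <- scale_df(base_time_df, 1.25)
      sp$temp_df <- scale_df(sp$temp_df, 1.25)
      sp$rh_df <- scale_df(sp$rh_df, 1.25)
      list(spec = sp)
    },
    temp_lag_2_3 = function(sp) { sp$weather_lag <- "lag23"; list(spec = sp) },
    temp_lag_4_6 = function(sp) { sp$weather_lag <- "lag46"; list(spec = sp) },
    exclude_above_p95 = function(sp) list(spec = sp, include_dates = keep_hi),
    exclude_below_p5 = function(sp) list(spec = sp, include_dates = keep_lo)
  )

  rows <- lapply(names(perturb), function(nm) {
    mod <- perturb[[nm]](spec)
    d <- build_design(series, mod$spec, holidays = holidays,
                      include_dates = mod$include_dates)
    fit <- fit_irls(d$X, d$y)
    est <- new_effect_estimate(fit, d, mod$spec, "sensitivity", delta)
    data.frame(perturbation = nm, er = est$er, lo = est$lo, hi = est$hi,
               beta = est$beta, se = est$se, n_obs = est$n_obs,
               pct_change_beta = 100 * (est$beta - base_est$beta) /
                 abs(base_est$beta),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "base") <- base_est
  out
}
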