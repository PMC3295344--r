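#' City profile for the synthetic-data generator
#'
#' Bundles the per-city scales the generator emulates: expected mean daily
#' deaths by cause, pollutant means and interquartile ranges, and weather
#' means/SDs.
#'
#' @param name city label.
#' @param deaths named numeric, expected mean daily deaths for `total`,
#'   `cvd`, `resp` (deaths/day, all > 0).
#' @param pollutant_means named numeric means for `pm10`, `no2`, `o3_8h`,
#'   `so2` (ug/m3) and `co` (ppm).
#' @param pollutant_iqrs named numeric IQRs, same units and names.
#' @param weather_means named numeric: `temp` (deg C), `rh` (%).
#' @param weather_sds named numeric marginal SDs for `temp`, `rh`.
#' @return object of class `"city_profile"`.
#' @export
city_profile <- function(name, deaths, pollutant_means, pollutant_iqrs,
                         weather_means = c(temp = 22.5, rh = 76),
                         weather_sds = c(temp = 6, rh = 10)) {
  need <- c("pm10", "no2", "o3_8h", "so2", "co")
  stopifnot(all(need %in% names(pollutant_means)),
            all(need %in% names(pollutant_iqrs)),
            all(c("total", "cvd", "resp") %in% names(deaths)))
  if (any(deaths <= 0) || any(pollutant_means[need] <= 0) ||
      any(pollutant_iqrs[need] <= 0))
    stop("death scales, pollutant means and IQRs must all be positive")
  structure(list(name = name, deaths = deaths,
                 pollutant_means = pollutant_means[need],
                 pollutant_iqrs = pollutant_iqrs[need],
                 weather_means = weather_means, weather_sds = weather_sds),
            class = "city_profile")
}

#' Default Pearl River Delta city profiles
#'
#' Four city profiles (Guangzhou, Foshan, Zhongshan, Zhuhai) with daily
#' death scales and pollutant means/IQRs at the levels reported for the
#' PRD in 2006--2008.
#'
#' @return named list of [city_profile()] objects.
#' @export
prd_city_profiles <- function() {
  list(
    guangzhou = city_profile("guangzhou",
      deaths = c(total = 83.2, cvd = 30.1, resp = 15.2),
      pollutant_means = c(pm10 = 81.0, no2 = 53.9, o3_8h = 78.2, so2 = 55.2, co = 1.35),
      pollutant_iqrs  = c(pm10 = 62.0, no2 = 33.1, o3_8h = 72.8, so2 = 35.2, co = 0.61)),
    foshan = city_profile("foshan",
      deaths = c(total = 24.5, cvd = 9.3, resp = 5.3),
      pollutant_means = c(pm10 = 121.3, no2 = 70.4, o3_8h = 70.7, so2 = 95.4, co = 1.65),
      pollutant_iqrs  = c(pm10 = 89.0, no2 = 39.1, o3_8h = 77.3, so2 = 73.2, co = 1.23)),
    zhongshan = city_profile("zhongshan",
      deaths = c(total = 20.7, cvd = 9.4, resp = 3.7),
      pollutant_means = c(pm10 = 64.2, no2 = 48.4, o3_8h = 85.7, so2 = 57.3, co = 1.20),
      pollutant_iqrs  = c(pm10 = 58.2, no2 = 42.4, o3_8h = 70.8, so2 = 72.1, co = 0.87)),
    zhuhai = city_profile("zhuhai",
      deaths = c(total = 8.5, cvd = 3.5, resp = 1.1),
      pollutant_means = c(pm10 = 43.5, no2 = 38.1, o3_8h = 85.5, so2 = 39.5, co = 1.29),
      pollutant_iqrs  = c(pm10 = 24.8, no2 = 34.2, o3_8h = 76.5, so2 = 40.0, co = 0.73))
  )
}

#' Default target cross-correlation matrix for the PRD
#'
#' Pearson correlations between daily pollutant concentrations,
#' temperature and RH at the levels observed in the city-merged PRD data
#' (O3 weakly correlated with the primary pollutants; NO2 strongly
#' correlated with PM10, SO2 and CO; RH negatively correlated with all
#' pollutants).
#'
#' @return symmetric 7 x 7 correlation matrix over
#'   `pm10, no2, o3_8h, so2, co, temp, rh`.
#' @export
prd_target_correlations <- function() {
  v <- c("pm10", "no2", "o3_8h", "so2", "co", "temp", "rh")
  R <- diag(7); dimnames(R) <- list(v, v)
  set <- function(a, b, x) { R[a, b] <<- x; R[b, a] <<- x }
  set("o3_8h", "no2", 0.17); set("o3_8h", "pm10", 0.36)
  set("o3_8h", "so2", 0.08); set("o3_8h", "co", -0.06)
  set("o3_8h", "temp", 0.30); set("o3_8h", "rh", -0.50)
  set("no2", "pm10", 0.82); set("no2", "so2", 0.82); set("no2", "co", 0.72)
  set("no2", "temp", -0.51); set("no2", "rh", -0.31)
  set("pm10", "so2", 0.71); set("pm10", "co", 0.64)
  set("pm10", "temp", -0.34); set("pm10", "rh", -0.41)
  set("so2", "co", 0.74); set("so2", "temp", -0.47); set("so2", "rh", -0.31)
  set("co", "temp", -0.52); set("co", "rh", -0.09)
  set("temp", "rh", 0.29)
  R
}

#' Simulation configuration
#'
#' Collects every knob of the synthetic multicity generator. Defaults are
#' the study conditions the generator emulates: a 2006--2008 window,
#' autumn-peaking ozone (share 0.32 of marginal variance, mid-October
#' peak), winter-peaking primary pollutants, strongly seasonal
#' temperature, overdispersed mortality (phi = 1.5), AR(1) day-to-day
#' persistence, a shared regional noise component giving cross-city
#' exposure correlations near the reported inter-station range, and
#' injected lag 1--2 ozone effects at the headline excess risks (0.81%,
#' 1.01%, 1.33% per 10 ug/m3 on total, cardiovascular and respiratory
#' mortality).
#'
#' @param n_days number of days (>= 366 so seasonal terms are
#'   identifiable).
#' @param start_date first calendar date.
#' @param true_beta nested list, `true_beta[[pollutant]][[cause]]` =
#'   log-relative-risk per ug/m3 applied to the lag 1--2 mean exposure.
#' @param seasonal_shares named numeric in \[0, 1): share of each
#'   variable's marginal variance carried by the annual sinusoid.
#' @param peak_doys named integer day-of-year of each variable's seasonal
#'   peak.
#' @param target_correlations symmetric PSD correlation matrix over the
#'   seven exposure/weather variables (the achieved total cross-sectional
#'   correlations, seasonality included).
#' @param mort_seasonal_amplitude log-scale amplitude of the mortality
#'   seasonal sinusoid.
#' @param mort_peak_doy day-of-year of the mortality seasonal peak
#'   (winter).
#' @param dow_offsets length-7 log-scale day-of-week offsets (Mon..Sun).
#' @param overdispersion variance inflation factor phi >= 1; counts are
#'   negative binomial with variance phi x mean when phi > 1.
#' @param ar_coef AR(1) coefficient of the daily noise (shared across
#'   variables so cross-correlations are preserved).
#' @param regional_weight share in \[0, 1\] of noise variance common to
#'   all cities.
#' @param sd_scale multiplier on all noise/marginal SDs (0 gives
#'   noise-free series).
#' @param flu_epidemics list of `c(start_day, length, intensity)`
#'   multiplicative epidemics on respiratory mortality.
#' @param flu_affects_total also bump total mortality by the respiratory
#'   share of the epidemic.
#' @param seed integer seed; same seed gives bit-identical output.
#' @return object of class `"simulation_config"`.
#' @export
simulation_config <- function(
    n_days = 1096L,
    start_date = as.Date("2006-01-01"),
    true_beta = list(o3_8h = list(total = log(1.0081) / 10,
                                  cvd = log(1.0101) / 10,
                                  resp = log(1.0133) / 10)),
    seasonal_shares = c(pm10 = 0.12, no2 = 0.12, o3_8h = 0.32, so2 = 0.12,
                        co = 0.12, temp = 0.78, rh = 0.18),
    peak_doys = c(pm10 = 15, no2 = 15, o3_8h = 288, so2 = 15, co = 15,
                  temp = 201, rh = 161),
    target_correlations = prd_target_correlations(),
    mort_seasonal_amplitude = 0.12,
    mort_peak_doy = 20,
    dow_offsets = numeric(7),
    overdispersion = 1.5,
    ar_coef = 0.5,
    regional_weight = 0.6,
    sd_scale = 1,
    flu_epidemics = list(c(20, 21, 1.5), c(385, 21, 1.5), c(750, 21, 1.5)),
    flu_affects_total = TRUE,
    seed = 1L) {
  if (n_days < 366)
    stop("n_days must be at least 366 for seasonal terms to be identifiable")
  if (overdispersion < 1) stop("overdispersion phi must be >= 1")
  R <- target_correlations
  if (!isTRUE(all.equal(R, t(R))) || any(abs(diag(R) - 1) > 1e-12))
    stop("target correlation matrix must be symmetric with unit diagonal")
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8)
    stop(sprintf("target correlation matrix is not positive semi-definite (min eigenvalue %.3g)",
                 min(ev)))
  if (any(seasonal_shares < 0 | seasonal_shares >= 1))
    stop("seasonal shares must lie in [0, 1)")
  if (ar_coef < 0 || ar_coef >= 1) stop("ar_coef must be in [0, 1)")
  structure(list(
    n_days = as.integer(n_days), start_date = as.Date(start_date),
    true_beta = true_beta, seasonal_shares = seasonal_shares,
    peak_doys = peak_doys, target_correlations = R,
    mort_seasonal_amplitude = mort_seasonal_amplitude,
    mort_peak_doy = mort_peak_doy, dow_offsets = dow_offsets,
    overdispersion = overdispersion, ar_coef = ar_coef,
    regional_weight = regional_weight, sd_scale = sd_scale,
    flu_epidemics = flu_epidemics, flu_affects_total = flu_affects_total,
    seed = as.integer(seed)), class = "simulation_config")
}

# Innovation correlation matrix that makes the TOTAL series correlations
# hit the target: target_ij = sqrt(v_i v_j) cos(dphase_ij) + sqrt((1-v_i)(1-v_j)) Rn_ij.
# Rounded published targets can push the solved matrix slightly indefinite;
# repaired by eigenvalue flooring and renormalization to a correlation matrix.
noise_correlation <- function(target, shares, peak_doys) {
  v <- rownames(target)
  s <- shares[v]
  cmat <- outer(peak_doys[v], peak_doys[v],
                function(a, b) cos(2 * pi * (a - b) / 365.25))
  seas <- outer(sqrt(s), sqrt(s)) * cmat
  noise_w <- outer(sqrt(1 - s), sqrt(1 - s))
  Rn <- (target - seas) / noise_w
  Rn[Rn > 0.999] <- 0.999
  Rn[Rn < -0.999] <- -0.999
  diag(Rn) <- 1
  Rn <- (Rn + t(Rn)) / 2
  e <- eigen(Rn, symmetric = TRUE)
  if (min(e$values) < 1e-8) {
    vals <- pmax(e$values, 1e-8)
    Rn <- e$vectors %*% diag(vals) %*% t(e$vectors)
    Rn <- stats::cov2cor(Rn)
    dimnames(Rn) <- dimnames(target)
  }
  Rn
}

# Correlated AR(1) noise, unit marginal variance, stationary.
ar1_noise <- function(n, R, ar) {
  k <- ncol(R)
  U <- chol(R)
  E <- matrix(stats::rnorm(n * k), n, k) %*% U
  if (ar > 0) {
    out <- E
    a <- sqrt(1 - ar^2)
    for (t in 2:n) out[t, ] <- ar * out[t - 1L, ] + a * E[t, ]
    E <- out
  }
  colnames(E) <- colnames(R)
  E
}

#' Simulate one city's daily exposure and weather series
#'
#' Each variable is an annual sinusoid (phase per `peak_doys`; ozone peaks
#' in autumn so the Sep--Nov mean exceeds the Dec--Aug mean) plus
#' cross-correlated AR(1) noise, truncated at zero (RH clamped to
#' \[0, 100\]). The innovation correlations are solved so that the total
#' series correlations approximate the configured target matrix,
#' seasonality included.
#'
#' @param config a [simulation_config()].
#' @param profile a [city_profile()].
#' @param seed integer seed (defaults to `config$seed`).
#' @param regional optional shared regional innovation matrix (used by
#'   [simulate_prd()]); when supplied, the city's noise is
#'   `sqrt(w) regional + sqrt(1-w) local` with `w = config$regional_weight`.
#' @return daily data frame: `date, pm10, no2, o3_8h, so2, co, temp, rh`.
#' @export
simulate_exposures <- function(config, profile, seed = config$seed,
                               regional = NULL) {
  stopifnot(inherits(config, "simulation_config"),
            inherits(profile, "city_profile"))
  vars <- rownames(config$target_correlations)
  n <- config$n_days
  dates <- config$start_date + 0:(n - 1L)
  doy <- as.POSIXlt(dates)$yday + 1

  sd_tot <- c(profile$pollutant_iqrs / (2 * stats::qnorm(0.75)),
              profile$weather_sds)[vars] * config$sd_scale
  means <- c(profile$pollutant_means, profile$weather_means)[vars]
  shares <- config$seasonal_shares[vars]
  amp <- sd_tot * sqrt(2 * shares)
  noise_sd <- sd_tot * sqrt(1 - shares)

  Rn <- noise_correlation(config$target_correlations, config$seasonal_shares,
                          config$peak_doys)
  set.seed(seed)
  E <- ar1_noise(n, Rn, config$ar_coef)
  if (!is.null(regional)) {
    w <- config$regional_weight
    E <- sqrt(w) * regional + sqrt(1 - w) * E
  }

  out <- data.frame(date = dates)
  for (v in vars) {
    seas <- amp[v] * cos(2 * pi * (doy - config$peak_doys[v]) / 365.25)
    x <- means[v] + seas + noise_sd[v] * E[, v]
    if (v == "rh") x <- pmin(pmax(x, 0), 100)
    else if (v != "temp") x <- pmax(x, 0)
    out[[v]] <- x
  }
  out
}

# Lag-window mean that falls back to the available lags (or the current
# day) at the start of the series, used only by the generator so the
# first days still receive an exposure signal. Days using a partial
# window are flagged by the caller.
partial_lag_mean <- function(x, lags) {
  n <- length(x)
  vapply(seq_len(n), function(t) {
    idx <- t - lags
    idx <- idx[idx >= 1]
    if (!length(idx)) idx <- t
    mean(x[idx])
  }, numeric(1))
}

#' Simulate daily death counts given an exposure series
#'
#' For each cause, counts are drawn with
#' \eqn{\log \mu_t = \log(scale) + \sum \beta (lag 1\textendash 2\; exposure)_t +
#' seasonal + DOW + \log(flu_t)}. With `overdispersion > 1` the draw is
#' negative binomial parameterized so the variance equals phi x mean;
#' otherwise Poisson. The first two days use the available lags only and
#' are flagged in the `partial_lag` attribute.
#'
#' @param exposures daily exposure data frame from [simulate_exposures()]
#'   (at least 3 days).
#' @param config a [simulation_config()].
#' @param profile a [city_profile()].
#' @param seed integer seed.
#' @param return_truth attach the true log-means as attribute
#'   `"true_log_mu"`.
#' @return `exposures` with `deaths_total`, `deaths_cvd`, `deaths_resp`
#'   columns appended; attribute `partial_lag` marks the first two days.
#' @export
simulate_mortality <- function(exposures, config, profile,
                               seed = scramble_seed(config$seed),
                               return_truth = FALSE) {
  n <- nrow(exposures)
  if (n < 3) stop("exposure series must cover at least 3 days")
  doy <- as.POSIXlt(as.Date(exposures$date))$yday + 1
  dow <- as.integer(format(as.Date(exposures$date), "%u"))
  seas <- config$mort_seasonal_amplitude *
    cos(2 * pi * (doy - config$mort_peak_doy) / 365.25)

  flu_resp <- rep(1, n); flu_total <- rep(1, n)
  resp_share <- profile$deaths["resp"] / profile$deaths["total"]
  for (ep in config$flu_epidemics) {
    idx <- seq(ep[1], min(n, ep[1] + ep[2] - 1L))
    idx <- idx[idx >= 1 & idx <= n]
    flu_resp[idx] <- flu_resp[idx] * ep[3]
    if (config$flu_affects_total)
      flu_total[idx] <- flu_total[idx] * (1 + resp_share * (ep[3] - 1))
  }

  exposure_lp <- function(cause) {
    lp <- rep(0, n)
    for (pol in names(config$true_beta)) {
      b <- config$true_beta[[pol]][[cause]]
      if (is.null(b) || b == 0) next
      if (!pol %in% names(exposures))
        stop(sprintf("exposure column '%s' required by true_beta is missing", pol))
      lp <- lp + b * partial_lag_mean(exposures[[pol]], c(1L, 2L))
    }
    lp
  }

  set.seed(seed)
  phi <- config$overdispersion
  draw <- function(mu) {
    if (phi > 1) stats::rnbinom(n, size = mu / (phi - 1), mu = mu)
    else stats::rpois(n, mu)
  }
  log_mu <- cbind(
    total = log(profile$deaths["total"]) + exposure_lp("total") + seas +
      config$dow_offsets[dow] + log(flu_total),
    cvd = log(profile$deaths["cvd"]) + exposure_lp("cvd") + seas +
      config$dow_offsets[dow],
    resp = log(profile$deaths["resp"]) + exposure_lp("resp") + seas +
      config$dow_offsets[dow] + log(flu_resp))

  out <- exposures
  out$deaths_total <- draw(exp(log_mu[, "total"]))
  out$deaths_cvd <- draw(exp(log_mu[, "cvd"]))
  out$deaths_resp <- draw(exp(log_mu[, "resp"]))
  attr(out, "partial_lag") <- seq_len(n) <= 2L
  if (return_truth) attr(out, "true_log_mu") <- log_mu
  out
}

#' Simulate a complete city (exposures plus mortality)
#'
#' @inheritParams simulate_exposures
#' @return daily series in the packaged CSV schema.
#' @export
simulate_city <- function(config, profile, seed = config$seed,
                          regional = NULL) {
  ex <- simulate_exposures(config, profile, seed = seed, regional = regional)
  simulate_mortality(ex, config, profile, seed = scramble_seed(seed))
}

#' Simulate the four-city region
#'
#' Cities share a regional noise component (weight
#' `config$regional_weight`) so cross-city exposure correlations resemble
#' the correlated monitoring-station measurements of a compact river-delta
#' region; city-specific noise and counts come from per-city seed
#' substreams derived from the single global seed.
#'
#' @param config a [simulation_config()].
#' @param profiles named list of [city_profile()]s.
#' @return named list of daily city series.
#' @export
simulate_prd <- function(config, profiles = prd_city_profiles()) {
  Rn <- noise_correlation(config$target_correlations, config$seasonal_shares,
                          config$peak_doys)
  set.seed(derive_seed(config$seed, 0L))
  regional <- ar1_noise(config$n_days, Rn, config$ar_coef)
  out <- vector("list", length(profiles))
  names(out) <- names(profiles)
  for (i in seq_along(profiles)) {
    out[[i]] <- simulate_city(config, profiles[[i]],
                              seed = derive_seed(config$seed, i),
                              regional = regional)
  }
  out
}

# Per-city/per-purpose substream seeds from one global integer seed.
derive_seed <- function(seed, i) {
  as.integer((as.numeric(seed) + 104729 * as.numeric(i)) %% 2147483647)
}

# Affine scramble onto a different lattice, so the mortality substream of
# one city can never coincide with the exposure substream of another
# (derive_seed steps by a fixed additive stride; an additive mortality
# offset would land back on that lattice).
scramble_seed <- function(seed) {
  as.integer((48271 * as.numeric(seed) + 3) %% 2147483647)
}

#' Simulate hourly pollutant measurements with missingness
#'
#' Hourly values follow the city's daily seasonal level plus a diurnal
#' sinusoid (afternoon ozone peak, morning primary-pollutant peak) and
#' noise; individual (date, hour, pollutant) records are then deleted at
#' random at the stated rate. Deterministic under the seed.
#'
#' @param config a [simulation_config()].
#' @param profile a [city_profile()].
#' @param missingness_rate fraction of hourly records deleted (set to
#'   `NA`).
#' @param n_days number of days (defaults to `config$n_days`).
#' @param seed integer seed.
#' @return data frame: `date`, `hour` (0--23), one column per pollutant.
#' @export
simulate_hourly <- function(config, profile, missingness_rate = 0,
                            n_days = config$n_days,
                            seed = derive_seed(config$seed, 99L)) {
  stopifnot(missingness_rate >= 0, missingness_rate < 1)
  dates <- config$start_date + 0:(n_days - 1L)
  doy <- as.POSIXlt(dates)$yday + 1
  grid <- expand.grid(hour = 0:23, date = dates)[, c("date", "hour")]
  pols <- names(profile$pollutant_means)
  peak_hour <- c(pm10 = 9, no2 = 9, o3_8h = 14, so2 = 9, co = 9)
  set.seed(seed)
  for (p in pols) {
    m <- profile$pollutant_means[p]
    seas <- m * 0.2 * cos(2 * pi * (doy - config$peak_doys[p]) / 365.25)
    base <- rep(m + seas, each = 24L)
    diurnal <- 0.25 * m * cos(2 * pi * (grid$hour - peak_hour[p]) / 24)
    x <- pmax(base + diurnal + stats::rnorm(nrow(grid), 0, 0.1 * m), 0)
    if (missingness_rate > 0)
      x[stats::runif(nrow(grid)) < missingness_rate] <- NA_real_
    grid[[p]] <- x
  }
  grid
}
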