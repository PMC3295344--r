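#' Daily 24-hour mean with a completeness rule
#'
#' Computes the arithmetic mean of available hourly values per calendar
#' date, valid only when at least `min_hours` of the 24 hours are present
#' (default 18); otherwise the day is missing. Used for PM10, NO2, SO2 and
#' CO.
#'
#' @param hourly data frame with columns `date` (Date), `hour` (0--23) and
#'   one column per pollutant; at most one record per (date, hour).
#' @param pollutant column name to aggregate.
#' @param min_hours minimum hours required for a valid daily mean.
#' @return data frame with columns `date` and `value` (NA when the
#'   completeness rule fails), one row per date present in `hourly`.
#' @export
daily_mean_24h <- function(hourly, pollutant, min_hours = 18L) {
  check_hourly(hourly, pollutant)
  agg_by_date(hourly, pollutant, hours = 0:23, min_present = min_hours)
}

#' Daily 8-hour daytime ozone mean
#'
#' Mean over the eight hourly values labelled 10:00--17:00 (interval-start
#' labels spanning 1000--1800 hours), valid when at least `min_hours` of
#' the eight are present (default 6); otherwise missing.
#'
#' @param hourly hourly data frame as in [daily_mean_24h()].
#' @param pollutant ozone column name (default `"o3"`).
#' @param window_hours the hour labels of the daytime window.
#' @param min_hours minimum window hours required.
#' @return data frame with columns `date` and `value`.
#' @export
daily_mean_o3_8h <- function(hourly, pollutant = "o3", window_hours = 10:17,
                             min_hours = 6L) {
  check_hourly(hourly, pollutant)
  agg_by_date(hourly, pollutant, hours = window_hours, min_present = min_hours)
}

check_hourly <- function(hourly, pollutant) {
  if (!all(c("date", "hour") %in% names(hourly)))
    stop("hourly data must have 'date' and 'hour' columns")
  if (!pollutant %in% names(hourly))
    stop(sprintf("pollutant column '%s' not found", pollutant))
  if (any(hourly$hour < 0 | hourly$hour > 23, na.rm = TRUE))
    stop("'hour' must be in 0..23")
  if (anyDuplicated(hourly[c("date", "hour")]))
    stop("at most one record per (date, hour) is allowed")
  invisible(TRUE)
}

agg_by_date <- function(hourly, pollutant, hours, min_present) {
  sub <- hourly[hourly$hour %in% hours, c("date", pollutant)]
  dates <- sort(unique(hourly$date))
  vals <- vapply(dates, function(d) {
    v <- sub[[pollutant]][sub$date == d]
    v <- v[!is.na(v)]
    if (length(v) >= min_present) mean(v) else NA_real_
  }, numeric(1))
  data.frame(date = dates, value = vals)
}

#' Average daily series across monitoring stations
#'
#' Per date and variable, the mean over stations with non-missing values;
#' missing only when every station is missing. Dates are aligned on the
#' union of station dates.
#'
#' @param series_list list of per-station data frames, each with `date`
#'   plus numeric variable columns.
#' @param variables variables to average; defaults to the union of
#'   non-`date` columns.
#' @return data frame with `date` plus the averaged variables.
#' @export
average_stations <- function(series_list, variables = NULL) {
  if (!length(series_list)) stop("need at least one station series")
  if (is.null(variables))
    variables <- unique(unlist(lapply(series_list, function(s) setdiff(names(s), "date"))))
  dates <- sort(unique(as.Date(unlist(lapply(series_list, function(s) as.character(s$date))))))
  out <- data.frame(date = dates)
  for (v in variables) {
    mats <- vapply(series_list, function(s) {
      m <- rep(NA_real_, length(dates))
      if (v %in% names(s)) m[match(as.Date(s$date), dates)] <- s[[v]]
      m
    }, numeric(length(dates)))
    mats <- matrix(mats, nrow = length(dates))
    out[[v]] <- rowMeans(mats, na.rm = TRUE)
    out[[v]][!is.finite(out[[v]])] <- NA_real_
  }
  out
}

#' Lag-window mean of a daily variable
#'
#' Value at day t is the mean of the variable at days \eqn{t - \ell} for
#' \eqn{\ell} in `lags`; missing whenever any constituent day is missing
#' (no partial windows), so the first `max(lags)` days are missing. The
#' series must be calendar-complete and date-sorted.
#'
#' @param series daily data frame with a `date` column.
#' @param variable column name.
#' @param lags set of non-negative integer lags, e.g. `c(1, 2)` for the
#'   mean over the previous two days.
#' @return numeric vector aligned with `series$date`.
#' @export
lag_window_mean <- function(series, variable, lags) {
  if (!variable %in% names(series))
    stop(sprintf("variable '%s' not found in series", variable))
  stopifnot(all(lags >= 0), all(lags == round(lags)))
  check_calendar(series)
  x <- series[[variable]]
  n <- length(x)
  acc <- matrix(NA_real_, n, length(lags))
  for (j in seq_along(lags)) {
    l <- lags[j]
    if (l == 0) acc[, j] <- x
    else acc[(l + 1):n, j] <- x[1:(n - l)]
  }
  rowMeans(acc)  # NA if any constituent missing
}

check_calendar <- function(series) {
  d <- as.Date(series$date)
  if (is.unsorted(d, strictly = TRUE))
    stop("series dates must be strictly increasing")
  if (length(d) > 1 && any(diff(d) != 1))
    stop("series must be calendar-complete (represent gaps as missing values)")
  invisible(TRUE)
}

#' Influenza epidemic indicator
#'
#' Binary indicator that is 1 when the 7-day moving average of daily
#' respiratory deaths exceeds (strictly) the 90th percentile of the
#' city-specific distribution of that moving average. The window is
#' centered (\eqn{t-3, \dots, t+3}) by default, shrinking at the series
#' ends; a trailing window is available as a switch. A switch also allows
#' the percentile to be taken over the raw counts instead of the moving
#' averages.
#'
#' @param respiratory_counts non-negative integer vector of daily
#'   respiratory deaths.
#' @param window `"centered"` (default) or `"trailing"`.
#' @param percentile_on `"moving_average"` (default) or `"raw"`.
#' @param prob percentile level (default 0.9).
#' @return integer vector of 0/1, same length as the input.
#' @export
influenza_indicator <- function(respiratory_counts,
                                window = c("centered", "trailing"),
                                percentile_on = c("moving_average", "raw"),
                                prob = 0.9) {
  window <- match.arg(window)
  percentile_on <- match.arg(percentile_on)
  y <- as.numeric(respiratory_counts)
  if (any(is.na(y))) stop("respiratory counts must be complete")
  n <- length(y)
  m <- vapply(seq_len(n), function(t) {
    idx <- if (window == "centered") (t - 3L):(t + 3L) else (t - 6L):t
    idx <- idx[idx >= 1L & idx <= n]
    mean(y[idx])
  }, numeric(1))
  ref <- if (percentile_on == "moving_average") m else y
  thr <- stats::quantile(ref, prob, type = 7, names = FALSE)
  as.integer(m > thr)
}

#' Pairwise-complete Pearson correlation between two series variables
#'
#' @param series daily data frame.
#' @param var_a,var_b column names.
#' @return correlation coefficient in \[-1, 1\].
#' @export
pearson_corr <- function(series, var_a, var_b) {
  for (v in c(var_a, var_b)) if (!v %in% names(series))
    stop(sprintf("variable '%s' not found in series", v))
  stats::cor(series[[var_a]], series[[var_b]], use = "pairwise.complete.obs",
             method = "pearson")
}

#' Label dates as ozone peak or nonpeak period
#'
#' September through November is the peak ozone period in the Pearl River
#' Delta (autumn maximum); December through August is nonpeak.
#'
#' @param dates Date vector.
#' @return character vector `"peak"`/`"nonpeak"`.
#' @export
label_periods <- function(dates) {
  m <- as.integer(format(as.Date(dates), "%m"))
  ifelse(m %in% 9:11, "peak", "nonpeak")
}

#' Merge cities into a single regional series
#'
#' Death counts are summed per date across cities; exposure and weather
#' variables are averaged (mean of non-missing cities, missing only when
#' all are missing), mirroring the city-merged analysis of summed
#' mortality and network-averaged environmental data.
#'
#' @param series_list list of per-city daily series sharing the packaged
#'   CSV schema.
#' @return merged daily series.
#' @export
merge_cities <- function(series_list) {
  if (!length(series_list)) stop("need at least one city series")
  count_cols <- grep("^deaths_", names(series_list[[1]]), value = TRUE)
  env_cols <- setdiff(names(series_list[[1]]), c("date", count_cols, "flu", "period"))
  merged <- average_stations(series_list, variables = env_cols)
  dates <- merged$date
  for (cc in count_cols) {
    mats <- vapply(series_list, function(s) {
      m <- rep(NA_real_, length(dates))
      if (cc %in% names(s)) m[match(as.Date(s$date), dates)] <- s[[cc]]
      m
    }, numeric(length(dates)))
    merged[[cc]] <- rowSums(matrix(mats, nrow = length(dates)))
  }
  merged
}

#' Prepare a daily series for regression
#'
#' Adds the influenza epidemic indicator (`flu`, from the series' own
#' respiratory counts), the peak/nonpeak period label (`period`), and the
#' public-holiday indicator (`holiday`) when a calendar is supplied.
#'
#' @param series daily series with `date` and `deaths_resp`.
#' @param holidays optional Date vector of public holidays.
#' @param flu_window,flu_percentile_on passed to [influenza_indicator()].
#' @return the series with `flu`, `period` (and `holiday`) columns added.
#' @export
prepare_series <- function(series, holidays = NULL,
                           flu_window = "centered",
                           flu_percentile_on = "moving_average") {
  check_calendar(series)
  if (!"deaths_resp" %in% names(series))
    stop("series must contain 'deaths_resp' to construct the influenza indicator")
  series$flu <- influenza_indicator(series$deaths_resp, window = flu_window,
                                    percentile_on = flu_percentile_on)
  series$period <- label_periods(series$date)
  if (!is.null(holidays))
    series$holiday <- as.integer(as.Date(series$date) %in% as.Date(holidays))
  series
}

#' Chinese statutory public holidays, 2006--2008
#'
#' The statutory holiday dates for 2006--2008 (New Year, Spring Festival,
#' Labour Day, National Day; plus Qingming, Dragon Boat and Mid-Autumn
#' from 2008), shipped as a plain-text calendar in `inst/extdata`.
#'
#' @param path optional path to an alternative calendar file (one ISO date
#'   per line, `#` comments allowed).
#' @return Date vector.
#' @export
read_holidays <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "cn_holidays_2006_2008.txt", package = "prdmort")
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  as.Date(lines[nzchar(lines)])
}
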