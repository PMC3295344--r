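make_hourly <- function(days, fill) {
  grid <- expand.grid(hour = 0:23, date = as.Date("2006-01-01") + 0:(days - 1))
  grid <- grid[, c("date", "hour")]
  grid$pm10 <- fill(nrow(grid))
  grid
}

test_that("24-hour daily means honour the 18-of-24 completeness rule", {
  h <- make_hourly(1, function(n) rep(10, n))
  h$pm10[1:6] <- NA  # 18 hours left, all equal 10
  expect_equal(daily_mean_24h(h, "pm10")$value, 10)
  h$pm10[7] <- NA    # 17 hours
  expect_true(is.na(daily_mean_24h(h, "pm10")$value))
  h2 <- make_hourly(1, function(n) 1:24)
  expect_equal(daily_mean_24h(h2, "pm10")$value, 12.5)
})

test_that("completeness rules agree with a brute-force recount under random missingness", {
  set.seed(42)
  h <- make_hourly(60, function(n) runif(n, 10, 100))
  h$pm10[runif(nrow(h)) < 0.35] <- NA
  got <- daily_mean_24h(h, "pm10")
  for (i in seq_len(nrow(got))) {
    v <- h$pm10[h$date == got$date[i]]
    v <- v[!is.na(v)]
    expected <- if (length(v) >= 18) mean(v) else NA_real_
    expect_equal(got$value[i], expected)
  }
  # same property for the 8-hour ozone window (6-of-8 rule)
  names(h)[3] <- "o3"
  got8 <- daily_mean_o3_8h(h)
  for (i in seq_len(nrow(got8))) {
    v <- h$o3[h$date == got8$date[i] & h$hour %in% 10:17]
    v <- v[!is.na(v)]
    expected <- if (length(v) >= 6) mean(v) else NA_real_
    expect_equal(got8$value[i], expected)
  }
})

test_that("the 8-hour ozone mean uses only the 1000-1800 window", {
  h <- make_hourly(1, function(n) rep(0, n))
  names(h)[3] <- "o3"
  h$o3[h$hour %in% 10:17] <- 100
  expect_equal(daily_mean_o3_8h(h)$value, 100)
  h$o3[h$hour %in% 10:12] <- NA  # 5 window hours left
  expect_true(is.na(daily_mean_o3_8h(h)$value))
  h2 <- make_hourly(1, function(n) rep(NA_real_, n))
  names(h2)[3] <- "o3"
  h2$o3[h2$hour %in% 10:15] <- c(60, 70, 80, 90, 100, 110)
  expect_equal(daily_mean_o3_8h(h2)$value, 85)
})

test_that("station averaging uses all non-missing stations", {
  d <- as.Date("2006-01-01") + 0:2
  s1 <- data.frame(date = d, pm10 = c(80, 80, NA))
  s2 <- data.frame(date = d, pm10 = c(100, NA, NA))
  expect_equal(average_stations(list(s1))$pm10, s1$pm10)
  avg <- average_stations(list(s1, s2))
  expect_equal(avg$pm10, c(90, 80, NA))
})

test_that("lag-window means require every constituent day", {
  s <- data.frame(date = as.Date("2006-01-01") + 0:9, x = c(100, 60, 1:8))
  expect_equal(lag_window_mean(s, "x", c(1, 2))[3], 80)
  expect_true(all(is.na(lag_window_mean(s, "x", c(1, 2))[1:2])))
  expect_equal(lag_window_mean(s, "x", 0), s$x)
  ramp <- data.frame(date = as.Date("2006-01-01") + 0:19, x = 1:20)
  got <- lag_window_mean(ramp, "x", c(4, 5, 6))
  expect_equal(got[7:20], (7:20) - 5)
  s$x[5] <- NA
  lw <- lag_window_mean(s, "x", c(1, 2))
  expect_true(all(is.na(lw[6:7])))  # windows touching the gap
  expect_false(is.na(lw[8]))
})

test_that("lag-window means commute with scalar multiplication", {
  set.seed(1)
  s <- data.frame(date = as.Date("2006-01-01") + 0:49, x = runif(50, 0, 100))
  s2 <- s; s2$x <- 3.7 * s2$x
  expect_equal(lag_window_mean(s2, "x", c(1, 2)),
               3.7 * lag_window_mean(s, "x", c(1, 2)))
})

test_that("influenza indicator is all zero for constant counts (strict inequality)", {
  expect_true(all(influenza_indicator(rep(5, 120)) == 0))
})

test_that("influenza indicator matches a brute-force enumeration", {
  y <- c(rep(5, 90), rep(50, 10))
  got <- influenza_indicator(y)
  # independent recount: centered 7-day averages, empirical 90th percentile
  m <- sapply(seq_along(y), function(t) {
    idx <- max(1, t - 3):min(length(y), t + 3)
    mean(y[idx])
  })
  expected <- as.integer(m > quantile(m, 0.9, type = 7))
  expect_identical(got, expected)
  expect_gt(sum(got), 0)
})

test_that("a single spike marks exactly the window positions covering it", {
  y <- rep(0, 99); y[50] <- 1000
  got <- influenza_indicator(y)
  expect_true(all(got[47:53] == 1))
  expect_true(all(got[-(47:53)] == 0))
})

test_that("trailing-window and raw-percentile variants are available", {
  y <- c(rep(5, 90), rep(50, 10))
  trail <- influenza_indicator(y, window = "trailing")
  expect_true(sum(trail) > 0)
  # trailing window reacts later than the centered one
  expect_gt(which(trail == 1)[1], which(influenza_indicator(y) == 1)[1] - 1)
  raw <- influenza_indicator(y, percentile_on = "raw")
  expect_true(all(raw %in% c(0L, 1L)))
})

test_that("pairwise-complete Pearson correlation behaves", {
  s <- data.frame(date = as.Date("2006-01-01") + 0:99, x = rnorm(100))
  s$y <- -s$x
  expect_equal(pearson_corr(s, "x", "x"), 1.0)
  expect_equal(pearson_corr(s, "x", "y"), -1.0)
  set.seed(9)
  n <- 10000
  z <- rnorm(n)
  big <- data.frame(date = as.Date("2006-01-01") + 0:(n - 1),
                    a = z + rnorm(n), b = z + rnorm(n))  # rho = 0.5
  expect_lt(abs(pearson_corr(big, "a", "b") - 0.5), 0.03)
})

test_that("period labels split September-November from December-August", {
  expect_equal(label_periods(as.Date("2007-10-15")), "peak")
  expect_equal(label_periods(as.Date("2007-12-01")), "nonpeak")
  expect_equal(label_periods(as.Date("2007-08-31")), "nonpeak")
  expect_equal(label_periods(as.Date("2007-09-01")), "peak")
  expect_equal(label_periods(as.Date("2007-11-30")), "peak")
})

test_that("merging cities sums deaths and averages exposures", {
  cfg <- flat_config(n_days = 370, sd_scale = 1)
  a <- simulate_city(cfg, toy_profile(), seed = 1)
  b <- simulate_city(cfg, toy_profile(), seed = 2)
  dup <- merge_cities(list(a, a))
  expect_equal(dup$deaths_total, 2 * a$deaths_total)
  expect_equal(dup$o3_8h, a$o3_8h)
  two <- merge_cities(list(a, b))
  expect_equal(two$deaths_total[5], a$deaths_total[5] + b$deaths_total[5])
  expect_equal(mean(two$o3_8h), mean(c(a$o3_8h, b$o3_8h)))
})

test_that("calendar gaps and unsorted dates are rejected", {
  s <- data.frame(date = as.Date("2006-01-01") + c(0, 1, 3), x = 1:3)
  expect_error(lag_window_mean(s, "x", 1), "calendar-complete")
  s2 <- data.frame(date = as.Date("2006-01-01") + c(1, 0, 2), x = 1:3)
  expect_error(lag_window_mean(s2, "x", 1), "strictly increasing")
})
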