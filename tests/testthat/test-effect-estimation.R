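test_that("excess-risk transformation matches closed forms", {
  z <- excess_risk(0, 1e-4, 10)
  expect_equal(unname(z["er"]), 0)
  expect_lt(z["lo"], 0); expect_gt(z["hi"], 0)
  expect_equal(unname(excess_risk(log(1.0064) / 10, 1e-4, 10)["er"]), 0.64,
               tolerance = 1e-10)
  # IQR scaling: a 0.81%/10 ug/m3 coefficient over a 72.8 ug/m3 increment
  expect_equal(unname(excess_risk(8.0673e-4, 1e-4, 72.8)["er"]), 6.05,
               tolerance = 0.005)
})

test_that("published ER (CI) rows invert to coefficients and round-trip", {
  b <- beta_from_er(0.64, 0.42, 0.86, 10)
  expect_equal(unname(b["beta"]), 6.3796e-4, tolerance = 1e-4)
  expect_equal(unname(b["se"]), 1.1153e-4, tolerance = 1e-4)
  expect_equal(unname(beta_from_er(0, -0.5, 0.5)["beta"]), 0)
  # round trip beta -> er -> beta (Wald CIs are symmetric on the log scale)
  for (beta in c(-5e-4, 3e-4, 2e-3)) {
    se <- 2e-4
    er <- excess_risk(beta, se, 10)
    bb <- beta_from_er(er["er"], er["lo"], er["hi"], 10)
    expect_equal(unname(bb), c(beta, se), tolerance = 1e-12)
    expect_equal(unname(excess_risk(bb["beta"], bb["se"], 10)), unname(er),
                 tolerance = 1e-12)
  }
  expect_error(beta_from_er(0.5, 1.0, 0.2), "malformed")
})

test_that("a single-pollutant fit recovers an injected city-level effect", {
  cfg <- simulation_config(seed = 101)
  s <- prepare_series(simulate_city(cfg, prd_city_profiles()$guangzhou),
                      holidays = read_holidays())
  est <- run_single_pollutant(s, "o3_8h", "total", scope = "guangzhou")
  truth <- log(1.0081) / 10
  expect_lt(abs(est$beta - truth), 4 * est$se)
  expect_equal(est$er, (exp(est$beta * 10) - 1) * 100)
  expect_equal(est$n_obs, 1094)  # first two days lost to the lag window
  s2 <- s; s2$o3_8h <- NA_real_
  expect_error(run_single_pollutant(s2, "o3_8h", "total"), "entirely missing")
})

test_that("two-pollutant models refuse collinear pairs, citing the correlation", {
  cfg <- simulation_config(seed = 102)
  s <- prepare_series(simulate_city(cfg, prd_city_profiles()$guangzhou),
                      holidays = read_holidays())
  err <- tryCatch(run_two_pollutant(s, "no2", "pm10", "total"),
                  error = conditionMessage)
  expect_match(err, "refused")
  expect_match(err, "0\\.[78]")  # the computed r appears in the message
})

test_that("adjusting for an independent co-pollutant leaves the estimate unchanged", {
  cfg <- simulation_config(seed = 103)
  s <- prepare_series(simulate_city(cfg, prd_city_profiles()$guangzhou),
                      holidays = read_holidays())
  set.seed(1)
  s$so2 <- rnorm(nrow(s), 50, 10)  # independent of exposure and outcome
  single <- run_single_pollutant(s, "o3_8h", "total")
  adj <- run_two_pollutant(s, "o3_8h", "so2", "total")
  expect_lt(abs(adj$beta - single$beta), single$se)
})

test_that("adjusting for a true confounder moves the estimate toward the truth", {
  set.seed(104)
  n <- 800
  s <- manual_series(n, seed = 104)
  z <- rnorm(n, 0, 20)
  s$o3_8h <- 80 + z + rnorm(n, 0, 25)
  s$pm10 <- 80 + z + rnorm(n, 0, 25)   # r about 0.4 < 0.6
  b1 <- 5e-4; b2 <- 15e-4
  x1 <- lag_window_mean(s, "o3_8h", c(1, 2))
  x2 <- lag_window_mean(s, "pm10", c(1, 2))
  mu <- exp(log(30) + b1 * ifelse(is.na(x1), 0, x1 - 80) +
              b2 * ifelse(is.na(x2), 0, x2 - 80))
  s$deaths_total <- rpois(n, mu)
  sp <- model_spec(use_flu = FALSE, use_holiday = FALSE, use_year = FALSE,
                   include_temp = FALSE, include_rh = FALSE,
                   time_df_per_year = 2)
  single <- run_single_pollutant(s, "o3_8h", "total", spec = sp)
  adj <- run_two_pollutant(s, "o3_8h", "pm10", "total", spec = sp)
  expect_lt(abs(adj$beta - b1), abs(single$beta - b1))
})

test_that("stratum-difference test reproduces published stratified significance", {
  pub <- published_stratified_ers()
  row_p <- pub[pub$cause == "resp" & pub$model == "single" & pub$stratum == "peak", ]
  row_np <- pub[pub$cause == "resp" & pub$model == "single" & pub$stratum == "nonpeak", ]
  bp <- beta_from_er(row_p$er, row_p$lo, row_p$hi)
  bnp <- beta_from_er(row_np$er, row_np$lo, row_np$hi)
  d <- stratum_difference(bp["beta"], bp["se"], bnp["beta"], bnp["se"])
  expect_lt(d["p"], 0.01)
  # identical strata: no difference
  expect_equal(unname(stratum_difference(1e-3, 1e-4, 1e-3, 1e-4)["p"]), 1)
})

test_that("stratified ozone analysis fits disjoint strata with the stated time dfs", {
  cfg <- simulation_config(seed = 105)
  m <- prepare_series(merge_cities(simulate_prd(cfg)), holidays = read_holidays())
  st <- run_stratified_o3(m, "total", adjust_pm10 = TRUE)
  expect_equal(st$peak$time_df, 2)
  expect_equal(st$nonpeak$time_df, 6)
  # Sep-Nov days over three years: 91 + 91 + 91
  expect_equal(st$peak$n_obs, 273)
  expect_equal(st$peak$n_obs + st$nonpeak$n_obs, 1094)
  expect_true(is.finite(st$difference["z"]))
  expect_gte(st$difference["p"], 0)
  expect_lte(st$difference["p"], 1)
})

test_that("df scaling rounds halves away from zero with a floor of one", {
  expect_equal(prdmort:::scale_df(6, 0.75), 5)
  expect_equal(prdmort:::scale_df(6, 1.25), 8)
  expect_equal(prdmort:::scale_df(3, 0.75), 2)
  expect_equal(prdmort:::scale_df(3, 1.25), 4)
  expect_equal(prdmort:::scale_df(1, 0.75), 1)
})

test_that("the sensitivity suite has exactly the ten standard perturbations", {
  # continuous exposure distribution so each 5% tail is non-degenerate
  s <- manual_series(1000, seed = 106)
  sens <- sensitivity_suite(s, model_spec())
  expect_equal(nrow(sens), 10)
  expect_setequal(sens$perturbation,
                  c("drop_temperature", "drop_rh", "drop_influenza",
                    "drop_holiday", "df_x0.75", "df_x1.25",
                    "temp_lag_2_3", "temp_lag_4_6",
                    "exclude_above_p95", "exclude_below_p5"))
  base <- attr(sens, "base")
  expect_s3_class(base, "effect_estimate")
  # percentile exclusions each remove about 5% of the days
  n_base <- base$n_obs
  n_hi <- sens$n_obs[sens$perturbation == "exclude_above_p95"]
  n_lo <- sens$n_obs[sens$perturbation == "exclude_below_p5"]
  expect_lt(abs((n_base - n_hi) - 0.05 * 1000), 8)
  expect_lt(abs((n_base - n_lo) - 0.05 * 1000), 8)
  # dropping influenza for a respiratory outcome is a no-op (not in model)
  expect_true(all(is.finite(sens$pct_change_beta)))
})

test_that("excess risk is strictly increasing in beta for fixed positive delta", {
  betas <- seq(-2e-3, 2e-3, length.out = 9)
  ers <- vapply(betas, function(b) excess_risk(b, 1e-4, 10)["er"], numeric(1))
  expect_true(all(diff(ers) > 0))
})
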