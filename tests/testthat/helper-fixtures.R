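# Shared fixtures built in code at test time.

# A small city profile with round numbers, for fast unit tests.
toy_profile <- function(total = 20, cvd = 8, resp = 4) {
  city_profile("toyville",
               deaths = c(total = total, cvd = cvd, resp = resp),
               pollutant_means = c(pm10 = 80, no2 = 50, o3_8h = 80, so2 = 50, co = 1.3),
               pollutant_iqrs = c(pm10 = 60, no2 = 35, o3_8h = 70, so2 = 40, co = 0.6))
}

# A configuration with all structure switched off: flat means, no noise,
# no seasonality, no epidemics, Poisson counts.
flat_config <- function(n_days = 500, seed = 1, phi = 1, true_beta = list(),
                        sd_scale = 0) {
  simulation_config(
    n_days = n_days, seed = seed, true_beta = true_beta,
    seasonal_shares = c(pm10 = 0, no2 = 0, o3_8h = 0, so2 = 0, co = 0,
                        temp = 0, rh = 0),
    mort_seasonal_amplitude = 0, overdispersion = phi,
    flu_epidemics = list(), sd_scale = sd_scale)
}

# A fully synthetic daily series with hand-controlled columns, for
# regression tests that need exact control over exposures.
manual_series <- function(n, seed = 1, mean_deaths = 30) {
  set.seed(seed)
  dates <- as.Date("2006-01-01") + 0:(n - 1)
  data.frame(
    date = dates,
    pm10 = 80 + rnorm(n, 0, 20), no2 = 50 + rnorm(n, 0, 15),
    o3_8h = 80 + rnorm(n, 0, 25), so2 = 50 + rnorm(n, 0, 15),
    co = pmax(1.3 + rnorm(n, 0, 0.3), 0),
    temp = 22 + rnorm(n, 0, 5), rh = pmin(pmax(75 + rnorm(n, 0, 8), 0), 100),
    deaths_total = rpois(n, mean_deaths),
    deaths_cvd = rpois(n, mean_deaths / 3),
    deaths_resp = rpois(n, mean_deaths / 6))
}

# Independent maximizer of the Poisson log-likelihood (warm-started,
# restarted BFGS), used as the brute-force oracle for the IRLS fitter.
brute_force_poisson <- function(X, y) {
  negll <- function(b) -sum(dpois(y, exp(drop(X %*% b)), log = TRUE))
  grad <- function(b) -drop(crossprod(X, y - exp(drop(X %*% b))))
  start <- c(log(mean(y) + 0.5), rep(0, ncol(X) - 1))
  o <- optim(start, negll, grad, method = "BFGS",
             control = list(reltol = 1e-16, maxit = 5000))
  o <- optim(o$par, negll, grad, method = "BFGS",
             control = list(reltol = 1e-16, maxit = 5000))
  o$par
}
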