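test_that("intercept-only fit returns the log of the mean count", {
  X <- cbind("(Intercept)" = rep(1, 3))
  fit <- fit_irls(X, c(1, 2, 3))
  expect_equal(unname(fit$coefficients), log(2), tolerance = 1e-10)
})

test_that("IRLS agrees with glm and with brute-force likelihood maximization", {
  set.seed(77)
  for (i in 1:20) {
    n <- 40 + sample(0:60, 1)
    p <- sample(2:4, 1)
    X <- cbind(1, matrix(rnorm(n * (p - 1)), n))
    colnames(X) <- c("(Intercept)", paste0("x", seq_len(p - 1)))
    beta0 <- c(1.5, rnorm(p - 1, 0, 0.3))
    y <- rpois(n, exp(drop(X %*% beta0)))
    fit <- fit_irls(X, y, overdispersion = FALSE)

    # glm stops at a looser deviance tolerance than this IRLS, so variance
    # quantities agree to ~1e-5 relative while coefficients agree much closer
    ref <- glm(y ~ X[, -1], family = poisson())
    expect_equal(unname(fit$coefficients), unname(coef(ref)), tolerance = 1e-7)
    expect_equal(unname(fit$se), unname(summary(ref)$coefficients[, 2]),
                 tolerance = 1e-4)
    expect_equal(fit$phi, summary(glm(y ~ X[, -1], family = quasipoisson()))$dispersion,
                 tolerance = 1e-4)
    expect_equal(fit$deviance, deviance(ref), tolerance = 1e-7)

    bf <- brute_force_poisson(X, y)
    expect_lt(max(abs(bf - fit$coefficients)), 1e-8)
  }
})

test_that("the quasi-Poisson scale is near 1 for equidispersed data", {
  set.seed(10)
  phis <- replicate(50, {
    X <- cbind("(Intercept)" = rep(1, 300), x = rnorm(300))
    y <- rpois(300, exp(2 + 0.3 * X[, 2]))
    fit_irls(X, y)$phi
  })
  expect_lt(abs(mean(phis) - 1), 0.05)
})

test_that("collinear designs are rejected naming the offending columns", {
  X <- cbind("(Intercept)" = rep(1, 30), a = 1:30, dup = 2 * (1:30))
  expect_error(fit_irls(X, rpois(30, 5)), "dup")
  expect_error(fit_irls(X[, 1:2], rpois(30, 5) - 100), "non-negative")
})

test_that("coefficients are exactly inversely rescaled under affine covariate rescaling", {
  set.seed(20)
  n <- 200
  X <- cbind("(Intercept)" = rep(1, n), x = rnorm(n, 50, 10))
  y <- rpois(n, exp(1 + 0.02 * X[, "x"]))
  f1 <- fit_irls(X, y)
  X2 <- X; X2[, "x"] <- (X[, "x"] - 5) / 10
  f2 <- fit_irls(X2, y)
  expect_equal(f2$coefficients[["x"]], 10 * f1$coefficients[["x"]],
               tolerance = 1e-8)
  expect_equal(f2$se[["x"]], 10 * f1$se[["x"]], tolerance = 1e-6)
})

test_that("Wald 95% CIs achieve near-nominal coverage on Poisson data", {
  set.seed(30)
  beta_true <- 0.05
  hits <- replicate(500, {
    n <- 200
    x <- rnorm(n)
    y <- rpois(n, exp(2 + beta_true * x))
    f <- fit_irls(cbind("(Intercept)" = rep(1, n), x = x), y)
    b <- f$coefficients[["x"]]; s <- f$se[["x"]]
    (beta_true >= b - 1.96 * s) && (beta_true <= b + 1.96 * s)
  })
  expect_gte(mean(hits), 0.93)
  expect_lte(mean(hits), 0.97)
})

test_that("PACF methods agree with each other and the reference implementation", {
  set.seed(40)
  x <- arima.sim(list(ar = 0.5), 5000)
  a <- pacf_values(x, 30, method = "durbin")
  b <- pacf_values(x, 30, method = "regression")
  expect_lt(max(abs(a - b)), 1e-10)
  ref <- drop(pacf(x, lag.max = 30, plot = FALSE)$acf)
  expect_lt(max(abs(a - ref)), 1e-8)
  expect_lt(abs(a[1] - 0.5), 0.05)
  expect_lt(max(abs(a[-1])), 0.06)
})

test_that("white-noise PACF stays within the asymptotic null band at most lags", {
  set.seed(41)
  x <- rnorm(5000)
  v <- pacf_values(x, 30)
  expect_gte(mean(abs(v) < 3 / sqrt(5000)), 0.9)
  expect_error(pacf_values(rnorm(20), 30), "too short")
  expect_error(pacf_values(rep(1, 100), 30), "constant")
})

test_that("df selection recovers a known seasonal signal within +/- 2 df", {
  set.seed(50)
  n <- 730
  hits <- replicate(100, {
    s <- manual_series(n, seed = sample.int(1e6, 1))
    # the truth is a natural spline on the 6-df knot set that oscillates at
    # every knot: inside the 6-df span, badly approximated with fewer knots
    b <- ns_basis(3:n, 6)  # the lag window leaves rows 3..n in the analysis
    kn <- c(b$boundary_knots[1], b$interior_knots, b$boundary_knots[2])
    fun <- splinefun(kn, 0.25 * c(0, 1, -1, 1, -1, 1, 0), method = "natural")
    f <- c(rep(0, 2), fun(3:n))
    s$deaths_total <- rpois(n, exp(log(30) + f))
    sp <- model_spec(cause = "total", pollutant = "o3_8h",
                     use_year = FALSE, use_dow = FALSE, use_flu = FALSE,
                     use_holiday = FALSE, include_temp = FALSE,
                     include_rh = FALSE)
    sel <- select_df(s, sp, grid = c(2, 4, 6, 8, 10), absolute = TRUE)
    abs(sel$choice - 6) <= 2
  })
  expect_gte(mean(hits), 0.8)
})

test_that("the selection rule prefers AIC, switches to PACF under overdispersion, and breaks ties to the smaller df", {
  tab <- data.frame(df = c(4, 6, 8), aic = c(10, 8, 9), gcv = c(3, 2, 2.5),
                    phi = c(1.0, 1.05, 1.1), abs_sum_pacf = c(0.9, 0.5, 0.2))
  sel <- prdmort:::selection_rule(tab, phi_threshold = 1.2)
  expect_equal(sel$choice, 6)
  expect_equal(sel$stage, "aic_gcv")
  tab$phi <- c(2, 2, 2)
  sel2 <- prdmort:::selection_rule(tab, phi_threshold = 1.2)
  expect_equal(sel2$choice, 8)
  expect_equal(sel2$stage, "pacf")
  tab$phi <- 1; tab$aic <- c(8, 8, 9)  # exact tie on AIC
  expect_equal(prdmort:::selection_rule(tab)$choice, 4)
})

test_that("a grid of size one is returned trivially with its criterion trace", {
  s <- manual_series(400, seed = 60)
  sp <- model_spec(use_flu = FALSE, use_holiday = FALSE)
  sel <- select_df(s, sp, grid = 7)
  expect_equal(sel$choice, 7)
  expect_equal(nrow(sel$table), 1)
  expect_true(all(c("aic", "gcv", "phi", "abs_sum_pacf") %in% names(sel$table)))
})

test_that("residual diagnostics flag omitted seasonality but not a well-specified fit", {
  set.seed(70)
  n <- 400
  # well-specified: flat Poisson, intercept-only; per-lag flag rate ~5%
  rates <- replicate(20, {
    f <- fit_irls(cbind("(Intercept)" = rep(1, n)), rpois(n, 20))
    mean(residual_diagnostics(f)$pacf$flagged)
  })
  expect_lt(mean(rates), 0.12)
  # strong omitted seasonality leaves autocorrelated residuals
  tindex <- seq_len(n)
  y <- rpois(n, exp(log(20) + 0.5 * cos(2 * pi * tindex / 365)))
  f <- fit_irls(cbind("(Intercept)" = rep(1, n)), y)
  d <- residual_diagnostics(f)
  expect_true(d$any_flag)
  expect_gt(abs(d$pacf$pacf[1]), d$bound)
  # short series are marked underpowered
  fs <- fit_irls(cbind("(Intercept)" = rep(1, 20)), rpois(20, 5))
  expect_true(residual_diagnostics(fs)$underpowered)
})
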