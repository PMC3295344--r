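#' Fit a Poisson log-link regression by IRLS with quasi-Poisson errors
#'
#' Maximizes the Poisson log-likelihood by iteratively reweighted least
#' squares. Overdispersion is quantified by the quasi-Poisson scale
#' \eqn{\hat\phi = \chi^2_{Pearson} / (n - p)}; when
#' `overdispersion = TRUE` (the default) reported standard errors are the
#' model-based ones multiplied by \eqn{\sqrt{\hat\phi}}. Convergence is
#' declared when the relative change in deviance falls below `tol`.
#'
#' @param X numeric design matrix including an intercept column; must have
#'   column names and full column rank (collinear columns are reported by
#'   name, never silently dropped).
#' @param y non-negative integer response (daily death counts).
#' @param offset optional numeric offset on the log scale.
#' @param overdispersion logical; scale standard errors by
#'   \eqn{\sqrt{\hat\phi}}.
#' @param tol relative deviance-change convergence tolerance.
#' @param max_iter maximum IRLS iterations.
#' @return An object of class `"irls_fit"`: coefficients, `se` (reported),
#'   `se_unscaled`, `vcov` (unscaled), `phi`, `deviance`, `loglik`, `aic`,
#'   `gcv` (\eqn{n D / (n-p)^2}), `fitted`, `residuals_deviance`, `n_obs`,
#'   `p`, `iterations`, `converged`.
#' @examples
#' X <- cbind("(Intercept)" = rep(1, 3))
#' fit_irls(X, c(1, 2, 3))$coefficients  # log(2)
#' @export
fit_irls <- function(X, y, offset = NULL, overdispersion = TRUE,
                     tol = 1e-10, max_iter = 100L) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  n <- length(y)
  if (nrow(X) != n) stop("nrow(X) must equal length(y)")
  if (any(is.na(X)) || any(is.na(y)))
    stop("design matrix and counts must be complete (drop incomplete rows first)")
  if (any(y < 0)) stop("counts must be non-negative")
  if (is.null(offset)) offset <- rep(0, n)
  p <- ncol(X)
  qrX <- qr(X)
  if (qrX$rank < p) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1L):p]]
    stop(sprintf("design matrix is rank deficient: column(s) %s are collinear with the others",
                 paste(sQuote(bad), collapse = ", ")))
  }
  if (n <= p) stop("need more observations than parameters")

  mu <- pmax(y, 0) + mean(y) / 2 + 0.1
  eta <- log(mu) - offset
  dev <- poisson_deviance(y, mu)
  dev_trace <- dev
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    w <- mu  # Poisson working weights, log link
    z <- eta + (y - mu) / mu
    sw <- sqrt(w)
    fit <- qr(X * sw)
    beta <- qr.coef(fit, z * sw)
    eta <- drop(X %*% beta)
    mu <- exp(eta + offset)
    dev_new <- poisson_deviance(y, mu)
    dev_trace <- c(dev_trace, dev_new)
    if (abs(dev_new - dev) / (abs(dev_new) + 0.1) < tol) {
      dev <- dev_new
      converged <- TRUE
      break
    }
    dev <- dev_new
  }
  if (!converged)
    stop(sprintf("IRLS did not converge in %d iterations; deviance trace: %s",
                 max_iter, paste(signif(utils::tail(dev_trace, 6), 8), collapse = " -> ")))

  w <- mu
  XtWX <- crossprod(X * sqrt(w))
  vcov_unscaled <- chol2inv(chol(XtWX))
  dimnames(vcov_unscaled) <- list(colnames(X), colnames(X))
  se_unscaled <- sqrt(diag(vcov_unscaled))
  phi <- sum((y - mu)^2 / mu) / (n - p)
  se <- if (overdispersion) se_unscaled * sqrt(phi) else se_unscaled
  ll <- sum(stats::dpois(y, mu, log = TRUE))
  dres <- sign(y - mu) * sqrt(pmax(poisson_deviance_units(y, mu), 0))

  structure(list(
    coefficients = stats::setNames(drop(beta), colnames(X)),
    se = stats::setNames(se, colnames(X)),
    se_unscaled = stats::setNames(se_unscaled, colnames(X)),
    vcov = vcov_unscaled,
    phi = phi,
    overdispersion = overdispersion,
    deviance = dev,
    loglik = ll,
    aic = -2 * ll + 2 * p,
    gcv = n * dev / (n - p)^2,
    fitted = mu,
    residuals_deviance = dres,
    n_obs = n, p = p,
    iterations = it, converged = converged
  ), class = "irls_fit")
}

# Per-observation deviance contributions 2*(y log(y/mu) - (y - mu)).
poisson_deviance_units <- function(y, mu) {
  term <- ifelse(y > 0, y * log(y / mu), 0)
  2 * (term - (y - mu))
}

poisson_deviance <- function(y, mu) sum(poisson_deviance_units(y, mu))

#' @export
print.irls_fit <- function(x, ...) {
  cat(sprintf("Quasi-Poisson IRLS fit: n = %d, p = %d, phi = %.3f\n",
              x$n_obs, x$p, x$phi))
  cat(sprintf("  deviance = %.2f, AIC = %.2f, GCV = %.4f, %d iterations\n",
              x$deviance, x$aic, x$gcv, x$iterations))
  invisible(x)
}

#' Partial autocorrelation function
#'
#' Partial autocorrelations of a series for lags `1:max_lag`, computed
#' either by the Durbin--Levinson recursion on the sample autocorrelations
#' or by solving the Yule--Walker (Toeplitz) system lag by lag and taking
#' the last coefficient. The two routes solve the same equations and agree
#' to numerical precision.
#'
#' @param x numeric series (e.g. deviance residuals).
#' @param max_lag largest lag; `length(x)` must exceed `max_lag + 1`.
#' @param method `"durbin"` or `"regression"`.
#' @return numeric vector of length `max_lag`, named by lag.
#' @export
pacf_values <- function(x, max_lag = 30L, method = c("durbin", "regression")) {
  method <- match.arg(method)
  x <- as.numeric(x)
  n <- length(x)
  if (n < max_lag + 2L)
    stop(sprintf("series of length %d is too short for PACF to lag %d (need at least %d)",
                 n, max_lag, max_lag + 2L))
  xc <- x - mean(x)
  denom <- sum(xc^2)
  if (denom == 0) stop("series is constant; PACF undefined")
  r <- vapply(seq_len(max_lag), function(k)
    sum(xc[seq_len(n - k)] * xc[(k + 1L):n]) / denom, numeric(1))

  out <- numeric(max_lag)
  if (method == "durbin") {
    phi <- numeric(0)
    for (k in seq_len(max_lag)) {
      if (k == 1L) {
        pk <- r[1]
        phi <- pk
      } else {
        pk <- (r[k] - sum(phi * r[(k - 1L):1L])) / (1 - sum(phi * r[seq_len(k - 1L)]))
        phi <- c(phi - pk * rev(phi), pk)
      }
      out[k] <- pk
    }
  } else {
    for (k in seq_len(max_lag)) {
      if (k == 1L) {
        out[k] <- r[1]
      } else {
        Rk <- stats::toeplitz(c(1, r[seq_len(k - 1L)]))
        out[k] <- solve(Rk, r[seq_len(k)])[k]
      }
    }
  }
  stats::setNames(out, seq_len(max_lag))
}

#' Select smoother degrees of freedom by AIC/GCV with a PACF override
#'
#' Implements the two-stage selection rule for the time-trend smoother:
#' fit the model at every candidate df, shortlist the AIC and GCV
#' minimizers, and -- if the quasi-Poisson scale of the AIC-best fit
#' exceeds `phi_threshold` -- switch to the candidate minimizing
#' \eqn{|\sum_{k=1}^{30} PACF_k|} of the deviance residuals instead.
#' Ties are broken toward the smallest df. The full criterion table is
#' returned for audit.
#'
#' @param series prepared daily series (see [prepare_series()]).
#' @param spec a [model_spec()] used as template; its time df field is
#'   overridden by each grid value.
#' @param grid numeric vector of candidate time df per year (or absolute
#'   df when `absolute = TRUE`).
#' @param absolute interpret `grid` as total df rather than df per year.
#' @param phi_threshold overdispersion trigger for the PACF stage.
#' @param pacf_lags number of residual PACF lags summed.
#' @param holidays optional holiday dates passed to the design builder.
#' @return list with `choice` (selected grid value), `stage`
#'   (`"aic_gcv"` or `"pacf"`), and `table` (df, aic, gcv, phi,
#'   abs_sum_pacf per candidate).
#' @export
select_df <- function(series, spec, grid, absolute = FALSE,
                      phi_threshold = 1.2, pacf_lags = 30L,
                      holidays = NULL) {
  if (!length(grid)) stop("df grid must be non-empty")
  grid <- sort(unique(grid))
  rows <- vector("list", length(grid))
  fits <- vector("list", length(grid))
  errs <- character(0)
  for (i in seq_along(grid)) {
    sp <- spec
    if (absolute) sp$time_df <- grid[i] else sp$time_df_per_year <- grid[i]
    res <- tryCatch({
      d <- build_design(series, sp, holidays = holidays)
      fit <- fit_irls(d$X, d$y)
      sp_abs <- abs(sum(pacf_values(fit$residuals_deviance, pacf_lags)))
      fits[[i]] <- fit
      data.frame(df = grid[i], aic = fit$aic, gcv = fit$gcv,
                 phi = fit$phi, abs_sum_pacf = sp_abs)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      errs <- c(errs, sprintf("df = %g: %s", grid[i], conditionMessage(res)))
    } else rows[[i]] <- res
  }
  tab <- do.call(rbind, rows)
  if (is.null(tab) || !nrow(tab))
    stop("all candidate fits failed:\n", paste(errs, collapse = "\n"))

  sel <- selection_rule(tab, phi_threshold)
  c(sel, list(table = tab, failures = if (length(errs)) errs else NULL))
}

# The two-stage decision on a criterion table (df, aic, gcv, phi,
# abs_sum_pacf): AIC minimizer (GCV minimizer recorded alongside), unless
# the AIC-best fit is overdispersed, in which case the |sum PACF|
# minimizer wins. Ties always break toward the smallest df.
selection_rule <- function(tab, phi_threshold = 1.2) {
  tab <- tab[order(tab$df), , drop = FALSE]
  pick_min <- function(vals) tab$df[which(vals == min(vals))[1L]]
  aic_best <- pick_min(tab$aic)
  gcv_best <- pick_min(tab$gcv)
  phi_at_aic <- tab$phi[tab$df == aic_best][1L]
  if (phi_at_aic > phi_threshold) {
    list(choice = pick_min(tab$abs_sum_pacf), stage = "pacf",
         aic_best = aic_best, gcv_best = gcv_best)
  } else {
    list(choice = aic_best, stage = "aic_gcv",
         aic_best = aic_best, gcv_best = gcv_best)
  }
}

#' Residual diagnostics for a fitted model
#'
#' Summarizes the deviance residuals: a residual-versus-time linear-trend
#' summary, the PACF table to `max_lag`, and a flag for any partial
#' autocorrelation exceeding the pointwise \eqn{2/\sqrt{n}} band. Never
#' raises on "bad" diagnostics -- it only flags.
#'
#' @param fit an `"irls_fit"`.
#' @param max_lag PACF lags to examine.
#' @return list with `n`, `underpowered` (`n < 35`), `pacf` (data frame of
#'   lag, value, flagged), `any_flag`, `bound`, and `time_trend`
#'   (slope of residual on observation index with its p-value).
#' @export
residual_diagnostics <- function(fit, max_lag = 30L) {
  stopifnot(inherits(fit, "irls_fit"))
  r <- fit$residuals_deviance
  n <- length(r)
  underpowered <- n < 35L
  pacf_tab <- NULL
  any_flag <- NA
  bound <- 2 / sqrt(n)
  if (n >= max_lag + 2L) {
    v <- pacf_values(r, max_lag)
    pacf_tab <- data.frame(lag = seq_len(max_lag), pacf = unname(v),
                           flagged = abs(v) > bound)
    any_flag <- any(pacf_tab$flagged)
  }
  tt <- stats::lm(r ~ seq_len(n))
  sl <- summary(tt)$coefficients
  list(n = n, underpowered = underpowered, bound = bound,
       pacf = pacf_tab, any_flag = any_flag,
       time_trend = c(slope = unname(sl[2, 1]), p = unname(sl[2, 4])))
}
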