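#' Natural cubic spline basis
#'
#' Builds a natural cubic spline basis with a given number of degrees of
#' freedom: piecewise cubic, C2-continuous, and constrained to be linear
#' beyond the boundary knots. Interior knots are placed at equally spaced
#' empirical quantiles of `x` (the convention of the time-series
#' air-pollution literature), boundary knots at the data range. The basis
#' has `df` columns excluding the intercept; the regression carries the
#' intercept once.
#'
#' The construction uses the reduced truncated-power representation: with
#' knots \eqn{t_1 < \dots < t_K} (boundary plus `df - 1` interior, so
#' \eqn{K = df + 1}), the columns are \eqn{x} and
#' \eqn{d_k(x) - d_{K-1}(x)} for \eqn{k = 1, \dots, K-2}, where
#' \eqn{d_k(x) = [(x - t_k)_+^3 - (x - t_K)_+^3] / (t_K - t_k)}. The cubic
#' and quadratic terms cancel beyond the boundary, giving natural (linear)
#' extrapolation on both sides. `x` is affinely mapped to the unit interval
#' internally for numerical conditioning.
#'
#' @param x numeric vector of evaluation points (the training data).
#' @param df positive integer; number of basis columns (excluding intercept).
#' @param interior_knots optional numeric vector of `df - 1` interior knots;
#'   defaults to quantiles of `x` at probabilities `(1:(df-1))/df`.
#' @param boundary_knots length-2 numeric; defaults to `range(x)`.
#' @return An object of class `"ns_basis"`: a list with `df`,
#'   `interior_knots`, `boundary_knots`, and `basis` (the n x df matrix at
#'   the training points). Evaluate at new points with [predict.ns_basis()].
#' @examples
#' b <- ns_basis(1:100, df = 4)
#' dim(b$basis)
#' @export
ns_basis <- function(x, df, interior_knots = NULL, boundary_knots = NULL) {
  if (length(df) != 1L || is.na(df) || df < 1 || df != round(df))
    stop("'df' must be a positive integer")
  df <- as.integer(df)
  xx <- x[!is.na(x)]
  n_distinct <- length(unique(xx))
  if (n_distinct < df + 1L)
    stop(sprintf("natural spline with df = %d needs at least %d distinct values; got %d",
                 df, df + 1L, n_distinct))
  if (is.null(boundary_knots)) boundary_knots <- range(xx)
  if (is.null(interior_knots)) {
    interior_knots <- if (df > 1L)
      unname(stats::quantile(xx, probs = seq_len(df - 1L) / df, type = 7))
    else numeric(0)
  }
  interior_knots <- sort(interior_knots)
  if (length(interior_knots) != df - 1L)
    stop(sprintf("expected %d interior knots for df = %d, got %d",
                 df - 1L, df, length(interior_knots)))
  if (df > 1L && (min(interior_knots) <= boundary_knots[1] ||
                  max(interior_knots) >= boundary_knots[2]))
    stop("interior knots must lie strictly inside the boundary knots")
  obj <- structure(
    list(df = df, interior_knots = interior_knots,
         boundary_knots = boundary_knots),
    class = "ns_basis")
  obj$basis <- ns_eval(obj, x)
  obj
}

# Evaluate the reduced truncated-power natural spline basis at x.
ns_eval <- function(object, x) {
  b <- object$boundary_knots
  scale <- b[2] - b[1]
  u <- (x - b[1]) / scale
  tau <- c(0, (object$interior_knots - b[1]) / scale, 1)
  K <- length(tau)
  out <- matrix(NA_real_, length(x), object$df)
  out[, 1L] <- u
  if (K > 2L) {
    dk <- function(k) {
      (pmax(u - tau[k], 0)^3 - pmax(u - tau[K], 0)^3) / (tau[K] - tau[k])
    }
    dlast <- dk(K - 1L)
    for (k in seq_len(K - 2L)) out[, k + 1L] <- dk(k) - dlast
  }
  colnames(out) <- paste0("ns", seq_len(object$df))
  out
}

#' Evaluate a natural spline basis at new points
#'
#' Consistent with the training-point matrix on the training data; linear
#' (natural) extrapolation outside the boundary knots.
#'
#' @param object an `"ns_basis"` object from [ns_basis()].
#' @param newx numeric vector of points at which to evaluate.
#' @param ... unused.
#' @return matrix with `length(newx)` rows and `df` columns.
#' @export
predict.ns_basis <- function(object, newx, ...) {
  ns_eval(object, newx)
}

#' @export
print.ns_basis <- function(x, ...) {
  cat(sprintf("Natural cubic spline basis: df = %d\n", x$df))
  cat(sprintf("  boundary knots: [%g, %g]\n",
              x$boundary_knots[1], x$boundary_knots[2]))
  if (length(x$interior_knots))
    cat("  interior knots:", paste(signif(x$interior_knots, 6), collapse = ", "), "\n")
  invisible(x)
}
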