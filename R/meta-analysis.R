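#' Cochran's Q homogeneity test across city estimates
#'
#' Fixed-effect inverse-variance framework: weights \eqn{w_i = 1/SE_i^2},
#' pooled \eqn{\bar\beta = \sum w_i \beta_i / \sum w_i},
#' \eqn{Q = \sum w_i (\beta_i - \bar\beta)^2}, with the p-value from the
#' upper tail of the chi-square distribution on \eqn{k - 1} df.
#'
#' @param beta numeric vector of city log-relative-risk estimates
#'   (k >= 2).
#' @param se their standard errors (all > 0).
#' @param labels optional city labels.
#' @return object of class `"homogeneity_result"`: `pooled_beta`,
#'   `pooled_se`, `Q`, `df`, `p`, and normalized `weights`.
#' @export
cochran_q <- function(beta, se, labels = NULL) {
  if (length(beta) != length(se)) stop("beta and se must have equal length")
  if (length(beta) < 2) stop("homogeneity test needs at least 2 estimates")
  if (any(is.na(beta)) || any(is.na(se))) stop("estimates must be complete")
  if (any(se <= 0)) {
    bad <- which(se <= 0)
    lab <- if (is.null(labels)) as.character(bad) else labels[bad]
    stop(sprintf("standard errors must be positive; offending entries: %s",
                 paste(lab, collapse = ", ")))
  }
  w <- 1 / se^2
  pooled <- sum(w * beta) / sum(w)
  Q <- sum(w * (beta - pooled)^2)
  k <- length(beta)
  structure(list(pooled_beta = pooled, pooled_se = 1 / sqrt(sum(w)),
                 Q = Q, df = k - 1L,
                 p = stats::pchisq(Q, k - 1L, lower.tail = FALSE),
                 weights = stats::setNames(w / sum(w), labels),
                 beta = beta, se = se, labels = labels),
            class = "homogeneity_result")
}

#' @export
print.homogeneity_result <- function(x, ...) {
  cat(sprintf("Cochran's Q homogeneity test: Q = %.3f on %d df, p = %.3f\n",
              x$Q, x$df, x$p))
  cat(sprintf("  fixed-effect pooled beta = %.4g (SE %.4g)\n",
              x$pooled_beta, x$pooled_se))
  invisible(x)
}

#' Fixed-effect inverse-variance pooled estimate
#'
#' @param beta,se estimate vectors as in [cochran_q()] (k >= 1 here).
#' @return named numeric: `beta` (pooled) and `se`
#'   (\eqn{1/\sqrt{\sum w_i}}).
#' @export
pool_fixed <- function(beta, se) {
  if (!length(beta) || length(beta) != length(se)) stop("invalid estimates")
  if (any(se <= 0)) stop("standard errors must be positive")
  w <- 1 / se^2
  c(beta = sum(w * beta) / sum(w), se = 1 / sqrt(sum(w)))
}

# Parse "0.64 (0.42, 0.86)" (tolerating en-dash/minus-sign variants) into
# c(er, lo, hi).
parse_er_ci <- function(s) {
  s <- gsub("–|−", "-", s)  # en-dash / minus sign variants
  m <- regmatches(s, gregexpr("-?[0-9]+\\.?[0-9]*", s))[[1]]
  if (length(m) != 3) stop(sprintf("cannot parse ER (CI) string: '%s'", s))
  as.numeric(m)
}

#' Homogeneity test from published per-city ER (CI) rows
#'
#' Reconstructs each city's coefficient and SE from a printed excess risk
#' with 95% CI via [beta_from_er()], then applies [cochran_q()]. Accepts
#' either numeric `er`, `lo`, `hi` columns or a single `er_ci` character
#' column in the printed "`ER (lo, hi)`" style (en-dash minus signs
#' tolerated).
#'
#' @param rows data frame with a `city` column plus either
#'   `er`/`lo`/`hi` or `er_ci`.
#' @param delta increment the printed ERs refer to (ug/m3).
#' @return a `"homogeneity_result"`.
#' @export
table_from_publication <- function(rows, delta = 10) {
  if (!"city" %in% names(rows)) stop("rows must have a 'city' column")
  if (!all(c("er", "lo", "hi") %in% names(rows))) {
    if (!"er_ci" %in% names(rows))
      stop("rows must have 'er','lo','hi' columns or an 'er_ci' column")
    parsed <- t(vapply(rows$er_ci, parse_er_ci, numeric(3)))
    rows$er <- parsed[, 1]; rows$lo <- parsed[, 2]; rows$hi <- parsed[, 3]
  }
  if (any(rows$lo > rows$hi))
    stop("malformed CI: lower endpoint exceeds upper endpoint")
  bs <- mapply(function(e, l, h) beta_from_er(e, l, h, delta),
               rows$er, rows$lo, rows$hi)
  cochran_q(bs["beta", ], bs["se", ], labels = rows$city)
}

#' Published city-specific excess risks (single-pollutant models)
#'
#' The per-city lag 1--2 day single-pollutant excess risks (percent, with
#' 95% CI, per 10 ug/m3) and the printed homogeneity p-values for the
#' four PRD cities, as shipped in `inst/extdata`. One row per
#' (cause, pollutant, city).
#'
#' @return data frame: `cause`, `pollutant`, `city`, `er`, `lo`, `hi`,
#'   `published_p`.
#' @export
published_city_ers <- function() {
  path <- system.file("extdata", "published_city_ers.tsv", package = "prdmort")
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Published stratified ozone excess risks (peak vs nonpeak)
#'
#' The city-merged stratified ozone excess risks (percent per 10 ug/m3,
#' 95% CI) by exposure period and PM10 adjustment, as shipped in
#' `inst/extdata`.
#'
#' @return data frame: `cause`, `model`, `stratum`, `er`, `lo`, `hi`.
#' @export
published_stratified_ers <- function() {
  path <- system.file("extdata", "published_stratified_ers.tsv",
                      package = "prdmort")
  utils::read.delim(path, stringsAsFactors = FALSE)
}
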