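#' Spearman rank correlation
#'
#' Product-moment correlation of midranks (average ranks for ties).
#'
#' @param x,y Numeric vectors of equal length (>= 3).
#' @param level Confidence level for the Fisher-z interval; set `NULL` to
#'   skip the interval (e.g. n < 4).
#' @return Object of class `correlation_result`: list with `rho`, `n`, `ci`
#'   (an [interval_estimate()] or `NULL`).
#' @export
spearman_rho <- function(x, y, level = 0.95) {
  if (length(x) != length(y)) stop("'x' and 'y' must have the same length")
  if (length(x) < 3L) stop("need at least 3 observations")
  if (anyNA(x) || anyNA(y)) stop("missing values not allowed")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("constant vector: rank correlation undefined")
  }
  rho <- stats::cor(x, y, method = "spearman")
  ci <- if (!is.null(level) && length(x) >= 4L) {
    spearman_ci(rho, length(x), level)
  } else NULL
  structure(list(rho = rho, n = length(x), ci = ci),
            class = "correlation_result")
}

#' Fisher-z confidence interval for a Spearman correlation
#'
#' Fisher transform `atanh(rho)` with the variance-inflated standard error
#' `sqrt(1.06 / (n - 3))` (the Fieller correction for rank correlations),
#' back-transformed with `tanh`. A degenerate `|rho| = 1` yields the point
#' interval at +/-1 with a warning.
#'
#' @param rho Spearman correlation.
#' @param n Sample size (>= 4).
#' @param level Confidence level.
#' @return An [interval_estimate()].
#' @export
spearman_ci <- function(rho, n, level = 0.95) {
  stopifnot(abs(rho) <= 1, n >= 4)
  if (abs(rho) == 1) {
    warning("|rho| = 1: degenerate interval")
    return(interval_estimate(rho, rho, rho, level))
  }
  z <- stats::qnorm(1 - (1 - level) / 2)
  se <- sqrt(1.06 / (n - 3))
  interval_estimate(rho, tanh(atanh(rho) - z * se), tanh(atanh(rho) + z * se),
                    level)
}

#' @export
print.correlation_result <- function(x, ...) {
  if (!is.null(x$ci)) {
    cat(sprintf("Spearman rho = %.3f (%g%% CI: %.3f-%.3f), n = %d\n",
                x$rho, 100 * x$ci$level, x$ci$lower, x$ci$upper, x$n))
  } else {
    cat(sprintf("Spearman rho = %.3f, n = %d\n", x$rho, x$n))
  }
  invisible(x)
}
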