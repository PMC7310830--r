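#' Interval estimate
#'
#' Lightweight container for a point estimate with a two-sided confidence
#' interval, used throughout the diagnostic-metric panel.
#'
#' @param point Point estimate.
#' @param lower,upper Interval bounds on the same scale as `point`. `NA` marks
#'   an undefined bound (e.g. a zero-cell likelihood-ratio interval).
#' @param level Confidence level in (0, 1).
#' @return An object of class `interval_estimate`: a list with elements
#'   `point`, `lower`, `upper`, `level`.
#' @export
interval_estimate <- function(point, lower, upper, level = 0.95) {
  stopifnot(is.numeric(level), length(level) == 1L, level > 0, level < 1)
  if (!is.na(point) && !is.na(lower) && !is.na(upper)) {
    if (lower > point + 1e-12 || upper < point - 1e-12) {
      stop("interval bounds must bracket the point estimate")
    }
  }
  structure(
    list(point = as.numeric(point), lower = as.numeric(lower),
         upper = as.numeric(upper), level = level),
    class = "interval_estimate"
  )
}

#' @export
print.interval_estimate <- function(x, digits = 4, ...) {
  cat(format(round(x$point, digits)),
      sprintf(" (%g%% CI: %s-%s)\n", 100 * x$level,
              format(round(x$lower, digits)), format(round(x$upper, digits))))
  invisible(x)
}

#' @export
format.interval_estimate <- function(x, digits = 3, scale = 1, ...) {
  fmt <- function(v) {
    if (is.na(v)) return("NA")
    format(round(v * scale, digits), nsmall = 0, trim = TRUE)
  }
  sprintf("%s (%s-%s)", fmt(x$point), fmt(x$lower), fmt(x$upper))
}

# internal: validate a numeric vector is finite and strictly positive
assert_positive <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x <= 0)) {
    stop(sprintf("'%s' must be finite and strictly positive", name),
         call. = FALSE)
  }
  invisible(x)
}

# internal: check marker/reference vectors form a valid two-class problem
assert_two_class <- function(marker, reference) {
  if (length(marker) != length(reference)) {
    stop("'marker' and 'reference' must have the same length", call. = FALSE)
  }
  if (anyNA(marker) || anyNA(reference)) {
    stop("missing values in 'marker' or 'reference'; exclude incomplete records first",
         call. = FALSE)
  }
  reference <- as.logical(reference)
  if (!any(reference) || all(reference)) {
    stop("both reference classes must be present", call. = FALSE)
  }
  reference
}
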