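#' Empirical ROC curve
#'
#' Operating points of the screen-positive rule `marker >= cutoff` over the
#' candidate set of observed marker values (plus `Inf` for the all-negative
#' endpoint), ordered by decreasing cutoff so FPR and TPR are non-decreasing
#' down the rows; endpoints (0, 0) and (1, 1) are always present.
#'
#' @param marker Numeric marker values.
#' @param reference Logical reference status.
#' @return Object of class `roc_curve`: a data frame with columns `cutoff`,
#'   `fpr`, `tpr`.
#' @export
roc_curve <- function(marker, reference) {
  reference <- assert_two_class(marker, reference)
  cutoffs <- c(Inf, sort(unique(marker), decreasing = TRUE))
  m <- sum(reference); k <- sum(!reference)
  tpr <- vapply(cutoffs, function(ct) sum(marker[reference] >= ct) / m, 1.0)
  fpr <- vapply(cutoffs, function(ct) sum(marker[!reference] >= ct) / k, 1.0)
  structure(data.frame(cutoff = cutoffs, fpr = fpr, tpr = tpr),
            class = c("roc_curve", "data.frame"))
}

#' @export
plot.roc_curve <- function(x, ...) {
  graphics::plot(x$fpr, x$tpr, type = "l", xlim = c(0, 1), ylim = c(0, 1),
                 xlab = "1 - specificity", ylab = "Sensitivity", ...)
  graphics::abline(0, 1, lty = 3, col = "grey50")
  invisible(x)
}

# internal: trapezoidal area under an roc_curve (ordered by increasing fpr)
trapezoid_auc <- function(roc) {
  o <- order(roc$fpr, roc$tpr)
  fpr <- roc$fpr[o]; tpr <- roc$tpr[o]
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

#' Empirical AUC (two-sample rank statistic)
#'
#' The probability that a randomly chosen diseased subject scores above a
#' randomly chosen non-diseased subject, ties counted 1/2 — the
#' Mann-Whitney form, identical to the trapezoidal area under the empirical
#' ROC curve. Computed via midranks in O(n log n).
#'
#' @inheritParams roc_curve
#' @return AUC in `[0, 1]`.
#' @export
empirical_auc <- function(marker, reference) {
  reference <- assert_two_class(marker, reference)
  r <- rank(marker)   # midranks handle ties as 1/2
  m <- as.numeric(sum(reference)); k <- as.numeric(sum(!reference))
  (sum(r[reference]) - m * (m + 1) / 2) / (m * k)
}

# internal: DeLong structural components. For each diseased subject i,
# V10[i] = mean_j psi(x_i, y_j) over non-diseased j (and symmetrically V01),
# psi = 1/0.5/0 for greater/tied/smaller. Computed from midranks.
delong_components <- function(marker, reference) {
  x <- marker[reference]; y <- marker[!reference]
  m <- length(x); k <- length(y)
  rall <- rank(c(x, y))
  rx <- rank(x); ry <- rank(y)
  v10 <- (rall[seq_len(m)] - rx) / k
  v01 <- 1 - (rall[m + seq_len(k)] - ry) / m
  list(v10 = v10, v01 = v01, m = m, k = k)
}

#' AUC confidence interval
#'
#' Default: normal-approximation interval from the nonparametric
#' structural-components (DeLong) variance of the rank AUC, truncated to
#' `[0, 1]`. `method = "bootstrap"` gives a percentile interval over seeded
#' case resamples instead (a sensitivity-analysis alternative). Perfectly
#' separated classes have zero DeLong variance; the interval then degenerates
#' to the point with a warning.
#'
#' @inheritParams roc_curve
#' @param level Confidence level.
#' @param method `"delong"` (default) or `"bootstrap"` (percentile).
#' @param n_boot,seed Bootstrap resamples and RNG seed (bootstrap method).
#' @return An [interval_estimate()] for the AUC.
#' @export
auc_ci <- function(marker, reference, level = 0.95,
                   method = c("delong", "bootstrap"),
                   n_boot = 2000, seed = NULL) {
  method <- match.arg(method)
  reference <- assert_two_class(marker, reference)
  auc <- empirical_auc(marker, reference)
  if (method == "delong") {
    if (sum(reference) < 2 || sum(!reference) < 2) {
      stop("DeLong variance needs at least 2 subjects per class")
    }
    cp <- delong_components(marker, reference)
    v <- stats::var(cp$v10) / cp$m + stats::var(cp$v01) / cp$k
    if (v <= 0) {
      warning("zero DeLong variance (perfect separation): degenerate interval")
      return(interval_estimate(auc, auc, auc, level))
    }
    z <- stats::qnorm(1 - (1 - level) / 2)
    half <- z * sqrt(v)
    interval_estimate(auc, max(0, auc - half), min(1, auc + half), level)
  } else {
    if (!is.null(seed)) set.seed(seed)
    n <- length(marker)
    reps <- replicate(n_boot, {
      idx <- sample.int(n, replace = TRUE)
      if (!any(reference[idx]) || all(reference[idx])) NA_real_
      else empirical_auc(marker[idx], reference[idx])
    })
    q <- stats::quantile(reps, c((1 - level) / 2, 1 - (1 - level) / 2),
                         na.rm = TRUE, names = FALSE)
    interval_estimate(auc, q[1], q[2], level)
  }
}

#' Qualitative AUC band
#'
#' Accuracy labels for AUC ranges: excellent `[0.9, 1]`, good `[0.8, 0.9)`,
#' fair `[0.7, 0.8)`, poor `[0.6, 0.7)`, fail `[0.5, 0.6)`. Shared boundaries
#' belong to the upper band. An AUC below 0.5 (worse than chance) is labelled
#' fail with a warning.
#'
#' @param auc AUC in `[0, 1]`.
#' @return One of `"excellent"`, `"good"`, `"fair"`, `"poor"`, `"fail"`.
#' @export
band_auc <- function(auc) {
  stopifnot(is.numeric(auc), length(auc) == 1L, auc >= 0, auc <= 1)
  if (auc < 0.5) {
    warning("AUC below 0.5: marker performs worse than chance")
    return("fail")
  }
  if (auc >= 0.9) "excellent"
  else if (auc >= 0.8) "good"
  else if (auc >= 0.7) "fair"
  else if (auc >= 0.6) "poor"
  else "fail"
}

#' AUC with confidence interval and qualitative band
#'
#' @inheritParams auc_ci
#' @return Object of class `auc_result`: list with `auc`, `ci`
#'   ([interval_estimate()]), `band`, `n_pos`, `n_neg`.
#' @export
auc_result <- function(marker, reference, level = 0.95,
                       method = c("delong", "bootstrap"),
                       n_boot = 2000, seed = NULL) {
  reference <- assert_two_class(marker, reference)
  ci <- auc_ci(marker, reference, level, method, n_boot, seed)
  structure(list(auc = ci$point, ci = ci, band = band_auc(ci$point),
                 n_pos = sum(reference), n_neg = sum(!reference)),
            class = "auc_result")
}

#' @export
print.auc_result <- function(x, ...) {
  cat(sprintf("AUC %.3f (%g%% CI: %.3f-%.3f), band: %s  [%d diseased / %d non-diseased]\n",
              x$auc, 100 * x$ci$level, x$ci$lower, x$ci$upper, x$band,
              x$n_pos, x$n_neg))
  invisible(x)
}

#' Youden-index optimal cutoff
#'
#' Maximizes J = sensitivity + specificity - 1 over the candidate cutoffs
#' (the observed marker values, with the `marker >= cutoff` rule). Ties are
#' broken toward the smallest cutoff, which maximizes sensitivity — the
#' appropriate choice for a screening tool.
#'
#' @inheritParams roc_curve
#' @param level Confidence level for the metric panel at the optimum.
#' @return Object of class `youden_cutoff`: list with `cutoff`, `youden_j`,
#'   `summary` (the full [summarize_confusion()] panel at the optimum), and
#'   the `roc` curve searched.
#' @export
optimal_cutoff_youden <- function(marker, reference, level = 0.95) {
  reference <- assert_two_class(marker, reference)
  if (length(unique(marker)) < 2L) {
    stop("all marker values identical: no informative cutoff exists")
  }
  roc <- roc_curve(marker, reference)
  finite <- is.finite(roc$cutoff)
  j <- roc$tpr - roc$fpr
  jf <- j[finite]; cf <- roc$cutoff[finite]
  best_j <- max(jf)
  # ties: smallest cutoff attaining the maximum
  cutoff <- min(cf[jf >= best_j - 1e-12])
  ct <- confusion_from_scores(marker, reference, cutoff)
  structure(list(cutoff = cutoff, youden_j = best_j,
                 summary = summarize_confusion(ct, cutoff, level), roc = roc),
            class = "youden_cutoff")
}

#' @export
print.youden_cutoff <- function(x, ...) {
  cat(sprintf("Youden-optimal cutoff: marker >= %g (J = %.3f)\n",
              x$cutoff, x$youden_j))
  print(x$summary)
  invisible(x)
}
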