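#' Univariable logistic probability model
#'
#' Fits reference status on the marker by maximum likelihood (IRLS via
#' `stats::glm`, convergence tolerance 1e-10, at most 100 iterations). This
#' is the probability model behind the calibration and optimism analyses:
#' `logit P(overweight) = intercept + slope * marker`. Perfect or
#' quasi-perfect separation (non-overlapping classes, or diverging
#' coefficients) is detected and raised as an explicit error.
#'
#' @param marker Numeric marker values.
#' @param reference Logical outcome.
#' @return Object of class `logistic_fit`: list with `intercept`, `slope`,
#'   `converged`, `n_iter`, `fitted` (training probabilities), `lp`
#'   (training linear predictor), `marker`, `reference`.
#' @export
fit_logistic_univariable <- function(marker, reference) {
  reference <- assert_two_class(marker, reference)
  if (min(marker[reference]) > max(marker[!reference]) ||
      max(marker[reference]) < min(marker[!reference])) {
    stop("perfect separation: logistic MLE does not exist", call. = FALSE)
  }
  fit <- suppressWarnings(
    stats::glm(reference ~ marker, family = stats::binomial(),
               control = stats::glm.control(epsilon = 1e-10, maxit = 100))
  )
  co <- stats::coef(fit)
  if (anyNA(co) || any(abs(co) > 1e6) || !fit$converged) {
    stop("quasi-perfect separation or non-convergence: coefficients diverge",
         call. = FALSE)
  }
  structure(
    list(intercept = unname(co[1]), slope = unname(co[2]),
         converged = fit$converged, n_iter = fit$iter,
         fitted = unname(stats::fitted(fit)),
         lp = unname(co[1] + co[2] * marker),
         marker = marker, reference = reference),
    class = "logistic_fit"
  )
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf("logit P(+) = %.4f + %.4f * marker  (converged in %d iterations)\n",
              x$intercept, x$slope, x$n_iter))
  invisible(x)
}

#' @rdname fit_logistic_univariable
#' @param fit A `logistic_fit`.
#' @param newmarker Marker values to predict at.
#' @export
predict_prob <- function(fit, newmarker) {
  stats::plogis(fit$intercept + fit$slope * newmarker)
}

#' Bootstrap optimism-corrected AUC
#'
#' Internal validation of discrimination by the standard bootstrap optimism
#' procedure: for each of `n_boot` resamples with replacement, refit the
#' univariable logistic model, take its apparent AUC on the resample and the
#' AUC of its linear predictor transported back to the original data; the
#' optimism is the mean of (apparent - test) over resamples, and the
#' corrected AUC is the original apparent AUC minus the mean optimism.
#' Because AUC is invariant to monotone transforms, with a positive fitted
#' slope this reduces exactly to mean(AUC_boot - AUC_original). Resamples
#' containing a single outcome class are redrawn (counted in `n_redrawn`), so
#' exactly `n_boot` valid resamples contribute.
#'
#' @inheritParams fit_logistic_univariable
#' @param n_boot Number of bootstrap resamples (default 1000).
#' @param seed RNG seed (required, for reproducibility).
#' @return Object of class `optimism_result`: list with `apparent_auc`,
#'   `mean_optimism`, `corrected_auc`, `n_boot`, `seed`, `n_redrawn`,
#'   `optimism` (per-resample values).
#' @export
bootstrap_optimism <- function(marker, reference, n_boot = 1000, seed) {
  reference <- assert_two_class(marker, reference)
  if (!is.numeric(n_boot) || length(n_boot) != 1L || n_boot < 1 ||
      n_boot != round(n_boot)) {
    stop("'n_boot' must be a positive integer")
  }
  if (missing(seed)) stop("'seed' is required for a reproducible bootstrap")
  set.seed(seed)
  n <- length(marker)
  apparent <- empirical_auc(marker, reference)
  separated <- min(marker[reference]) > max(marker[!reference]) ||
    max(marker[reference]) < min(marker[!reference])

  optimism <- numeric(n_boot)
  n_redrawn <- 0L
  for (b in seq_len(n_boot)) {
    repeat {
      idx <- sample.int(n, replace = TRUE)
      if (any(reference[idx]) && !all(reference[idx])) break
      n_redrawn <- n_redrawn + 1L
    }
    mb <- marker[idx]; rb <- reference[idx]
    if (separated) {
      # rank statistic saturated: model ordering is the marker ordering
      optimism[b] <- empirical_auc(mb, rb) - apparent
    } else {
      fb <- tryCatch(fit_logistic_univariable(mb, rb), error = function(e) NULL)
      if (is.null(fb)) {
        # resample separated: linear predictor ordering = marker ordering
        # (up to sign); use the sign of the marker-outcome association
        s <- if (empirical_auc(mb, rb) >= 0.5) 1 else -1
        apparent_b <- empirical_auc(s * mb, rb)
        test_b <- empirical_auc(s * marker, reference)
      } else {
        apparent_b <- empirical_auc(fb$lp, rb)
        test_b <- empirical_auc(predict_prob(fb, marker), reference)
      }
      optimism[b] <- apparent_b - test_b
    }
  }
  mean_opt <- mean(optimism)
  structure(
    list(apparent_auc = apparent, mean_optimism = mean_opt,
         corrected_auc = apparent - mean_opt, n_boot = n_boot, seed = seed,
         n_redrawn = n_redrawn, optimism = optimism),
    class = "optimism_result"
  )
}

#' @export
print.optimism_result <- function(x, ...) {
  cat(sprintf(
    "Apparent AUC %.4f; mean optimism %.4f over %d resamples (seed %s); corrected AUC %.4f\n",
    x$apparent_auc, x$mean_optimism, x$n_boot, format(x$seed), x$corrected_auc))
  if (x$n_redrawn > 0)
    cat(sprintf("  (%d single-class resamples redrawn)\n", x$n_redrawn))
  invisible(x)
}

# internal: Hosmer-Lemeshow grouped chi-square from observed events,
# expected events and bin sizes
hl_statistic <- function(obs, exp_, nb) {
  sum((obs - exp_)^2 / (exp_ * (1 - exp_ / nb)))
}

#' Calibration of predicted probabilities
#'
#' Groups subjects into `n_bins` equal-count bins of predicted probability
#' and compares observed event rates with mean predictions: the
#' Hosmer-Lemeshow statistic `sum((O - E)^2 / (E (1 - E/n_bin)))` on
#' `n_bins - 2` degrees of freedom, plus the calibration slope and intercept
#' from refitting the outcome on the model's linear predictor. Bins whose
#' expected count is zero are collapsed into their neighbour (with a warning
#' and a df adjustment). On its own training data a logistic MLE has
#' calibration slope 1 and intercept 0 by construction.
#'
#' @param fit A converged [fit_logistic_univariable()] model.
#' @param marker,reference Evaluation data (defaults: the training data).
#' @param n_bins Number of probability bins (default 10, >= 2).
#' @return Object of class `calibration_result`: list with `bins` (data
#'   frame: `mean_predicted`, `observed_rate`, `n`, `observed`, `expected`),
#'   `statistic`, `df`, `p_value`, `slope`, `intercept`, `n`.
#' @export
calibration_assess <- function(fit, marker = fit$marker,
                               reference = fit$reference, n_bins = 10) {
  stopifnot(inherits(fit, "logistic_fit"), fit$converged)
  if (n_bins < 2) stop("'n_bins' must be at least 2")
  reference <- as.logical(reference)
  p <- predict_prob(fit, marker)
  n <- length(p)

  # equal-count bins by quantiles of predicted probability
  breaks <- unique(stats::quantile(p, probs = seq(0, 1, length.out = n_bins + 1)))
  if (length(breaks) < 3) stop("predicted probabilities too tied to form bins")
  grp <- cut(p, breaks = breaks, include.lowest = TRUE, labels = FALSE)

  agg <- function(v, g) as.numeric(tapply(v, g, sum))
  nb <- as.numeric(table(grp))
  obs <- agg(as.numeric(reference), grp)
  exp_ <- agg(p, grp)
  mean_pred <- exp_ / nb

  # collapse bins with zero expected (or zero complement) into the neighbour
  degenerate <- function(e, m) e <= 0 | e >= m
  while (any(degenerate(exp_, nb)) && length(nb) > 2) {
    i <- which(degenerate(exp_, nb))[1]
    j <- if (i == 1) 2L else i - 1L
    nb[j] <- nb[j] + nb[i]; obs[j] <- obs[j] + obs[i]; exp_[j] <- exp_[j] + exp_[i]
    nb <- nb[-i]; obs <- obs[-i]; exp_ <- exp_[-i]
    warning("collapsed a degenerate calibration bin; degrees of freedom adjusted")
  }
  mean_pred <- exp_ / nb
  g <- length(nb)
  statistic <- hl_statistic(obs, exp_, nb)
  df <- g - 2
  p_value <- stats::pchisq(statistic, df = df, lower.tail = FALSE)

  # calibration slope/intercept: logistic refit of outcome on linear predictor
  lp <- fit$intercept + fit$slope * marker
  refit <- suppressWarnings(
    stats::glm(reference ~ lp, family = stats::binomial(),
               control = stats::glm.control(epsilon = 1e-12, maxit = 100)))
  co <- stats::coef(refit)

  structure(
    list(bins = data.frame(mean_predicted = mean_pred, observed_rate = obs / nb,
                           n = nb, observed = obs, expected = exp_),
         statistic = statistic, df = df, p_value = p_value,
         slope = unname(co[2]), intercept = unname(co[1]), n = n),
    class = "calibration_result"
  )
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf(
    "Hosmer-Lemeshow chi-square %.3f on %d df, p = %.4f (n = %d)\n",
    x$statistic, x$df, x$p_value, x$n))
  cat(sprintf("Calibration slope %.4f, intercept %.4f\n", x$slope, x$intercept))
  invisible(x)
}

#' @export
plot.calibration_result <- function(x, ...) {
  graphics::plot(x$bins$mean_predicted, x$bins$observed_rate,
                 xlim = c(0, 1), ylim = c(0, 1), pch = 19,
                 xlab = "Predicted probability", ylab = "Observed rate", ...)
  graphics::abline(0, 1, lty = 3, col = "grey50")
  invisible(x)
}
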