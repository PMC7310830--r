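#' Confusion table at a screening cutoff
#'
#' Cross-tabulates a continuous screening marker, dichotomized at a cutoff,
#' against the binary reference classification. A subject is screen-positive
#' when `marker >= cutoff` (the convention behind cutoffs printed as
#' ">= 27.75").
#'
#' @param marker Numeric marker values (e.g. MUAC in cm).
#' @param reference Logical reference status (`TRUE` = diseased, here
#'   overweight including obesity by BMI Z-score).
#' @param cutoff Screening threshold in marker units.
#' @return Object of class `confusion_table`: list with counts `tp`, `fp`,
#'   `fn`, `tn` and the `cutoff`.
#' @examples
#' confusion_from_scores(c(28, 26), c(TRUE, FALSE), 27)
#' @export
confusion_from_scores <- function(marker, reference, cutoff) {
  reference <- assert_two_class(marker, reference)
  stopifnot(is.numeric(cutoff), length(cutoff) == 1L, is.finite(cutoff))
  pos <- marker >= cutoff
  confusion_table(tp = sum(pos & reference), fp = sum(pos & !reference),
                  fn = sum(!pos & reference), tn = sum(!pos & !reference),
                  cutoff = cutoff)
}

#' @rdname confusion_from_scores
#' @param tp,fp,fn,tn Cell counts (non-negative, not all zero).
#' @export
confusion_table <- function(tp, fp, fn, tn, cutoff = NA_real_) {
  counts <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("confusion counts must be non-negative integers")
  }
  if (sum(counts) == 0) stop("confusion table is empty")
  structure(list(tp = tp, fp = fp, fn = fn, tn = tn, cutoff = cutoff),
            class = "confusion_table")
}

#' @export
print.confusion_table <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2,
              dimnames = list(`screen` = c("positive", "negative"),
                              `reference` = c("diseased", "non-diseased")))
  if (!is.na(x$cutoff)) cat(sprintf("Screen-positive rule: marker >= %g\n", x$cutoff))
  print(m)
  invisible(x)
}

#' Exact (Clopper-Pearson) binomial confidence interval
#'
#' The exact interval from beta-distribution tail quantiles:
#' lower = qbeta(alpha/2; x, n-x+1), upper = qbeta(1-alpha/2; x+1, n-x),
#' with lower = 0 at x = 0 and upper = 1 at x = n.
#'
#' @param successes,trials Binomial counts, `0 <= successes <= trials`.
#' @param level Confidence level (default 0.95).
#' @return An [interval_estimate()] on the proportion scale.
#' @examples
#' proportion_ci_exact(112, 123)   # (0.846, 0.955)
#' @export
proportion_ci_exact <- function(successes, trials, level = 0.95) {
  if (trials < 1 || successes < 0 || successes > trials ||
      successes != round(successes) || trials != round(trials)) {
    stop("need integer counts with 0 <= successes <= trials, trials >= 1")
  }
  alpha <- 1 - level
  lower <- if (successes == 0) 0 else
    stats::qbeta(alpha / 2, successes, trials - successes + 1)
  upper <- if (successes == trials) 1 else
    stats::qbeta(1 - alpha / 2, successes + 1, trials - successes)
  interval_estimate(successes / trials, lower, upper, level)
}

#' Log-method confidence interval for a likelihood ratio
#'
#' Simel-type interval: `exp(log(LR) +/- z * SE)` with
#' `SE^2 = 1/tp - 1/(tp+fn) + 1/fp - 1/(fp+tn)` for LR+ and
#' `SE^2 = 1/fn - 1/(tp+fn) + 1/tn - 1/(fp+tn)` for LR-.
#'
#' @param table A [confusion_table()].
#' @param which `"positive"` or `"negative"`.
#' @param level Confidence level.
#' @return An [interval_estimate()]; bounds are `NA` (with a message in
#'   `attr(, "note")`) when a zero cell makes the variance infinite.
#' @export
likelihood_ratio_ci <- function(table, which = c("positive", "negative"),
                                level = 0.95) {
  which <- match.arg(which)
  tp <- table$tp; fp <- table$fp; fn <- table$fn; tn <- table$tn
  ndis <- tp + fn; nnon <- fp + tn
  if (which == "positive") {
    lr <- (tp / ndis) / (fp / nnon)
    cells <- c(tp, fp)
    v <- 1 / tp - 1 / ndis + 1 / fp - 1 / nnon
  } else {
    lr <- (fn / ndis) / (tn / nnon)
    cells <- c(fn, tn)
    v <- 1 / fn - 1 / ndis + 1 / tn - 1 / nnon
  }
  if (any(cells == 0) || !is.finite(lr) || lr <= 0) {
    out <- interval_estimate(lr, NA_real_, NA_real_, level)
    attr(out, "note") <- "zero cell: log-method variance undefined"
    return(out)
  }
  z <- stats::qnorm(1 - (1 - level) / 2)
  se <- sqrt(v)
  interval_estimate(lr, exp(log(lr) - z * se), exp(log(lr) + z * se), level)
}

#' Diagnostic-metric panel with confidence intervals
#'
#' Computes sensitivity TP/(TP+FN), specificity TN/(TN+FP), PPV TP/(TP+FP),
#' NPV TN/(TN+FN), accuracy (TP+TN)/n, Youden index J = sensitivity +
#' specificity - 1, LR+ = sensitivity/(1-specificity) and
#' LR- = (1-sensitivity)/specificity from a confusion table. Proportions get
#' exact Clopper-Pearson intervals; likelihood ratios get log-method
#' intervals. A metric with a zero denominator is reported as `NA` (explicitly
#' undefined), never silently dropped.
#'
#' @param table A [confusion_table()].
#' @param cutoff Marker cutoff the table was built at (for display; taken
#'   from the table when omitted).
#' @param level Confidence level.
#' @return Object of class `diag_summary`: a list of [interval_estimate()]s
#'   (`sensitivity`, `specificity`, `ppv`, `npv`, `accuracy`, `youden_j`,
#'   `lr_pos`, `lr_neg`) plus `cutoff`, `table`, `n`.
#' @examples
#' summarize_confusion(confusion_table(tp = 112, fp = 71, fn = 11, tn = 657))
#' @export
summarize_confusion <- function(table, cutoff = table$cutoff, level = 0.95) {
  stopifnot(inherits(table, "confusion_table"))
  tp <- table$tp; fp <- table$fp; fn <- table$fn; tn <- table$tn
  n <- tp + fp + fn + tn

  prop_or_na <- function(x, d) {
    if (d == 0) interval_estimate(NA_real_, NA_real_, NA_real_, level)
    else proportion_ci_exact(x, d, level)
  }
  sens <- prop_or_na(tp, tp + fn)
  spec <- prop_or_na(tn, tn + fp)
  ppv  <- prop_or_na(tp, tp + fp)
  npv  <- prop_or_na(tn, tn + fn)
  acc  <- prop_or_na(tp + tn, n)
  youden <- interval_estimate(sens$point + spec$point - 1, NA_real_,
                              NA_real_, level)

  structure(
    list(sensitivity = sens, specificity = spec, ppv = ppv, npv = npv,
         accuracy = acc, youden_j = youden,
         lr_pos = likelihood_ratio_ci(table, "positive", level),
         lr_neg = likelihood_ratio_ci(table, "negative", level),
         cutoff = cutoff, table = table, n = n, level = level),
    class = "diag_summary"
  )
}

#' @export
print.diag_summary <- function(x, ...) {
  if (!is.na(x$cutoff)) {
    cat(sprintf("Diagnostic panel at cutoff >= %g (n = %d)\n", x$cutoff, x$n))
  } else {
    cat(sprintf("Diagnostic panel (n = %d)\n", x$n))
  }
  df <- as.data.frame(x)
  print(df, row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
as.data.frame.diag_summary <- function(x, ...) {
  pct <- c("sensitivity", "specificity", "ppv", "npv", "accuracy")
  metrics <- c(pct, "youden_j", "lr_pos", "lr_neg")
  data.frame(
    metric = metrics,
    point = vapply(x[metrics], function(e) e$point, 1.0),
    lower = vapply(x[metrics], function(e) e$lower, 1.0),
    upper = vapply(x[metrics], function(e) e$upper, 1.0),
    stringsAsFactors = FALSE
  )
}
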