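# The printed study contingency table used as a fixture throughout:
# 112 true positives, 71 false positives, 11 false negatives, 657 true
# negatives (n = 851, 123 diseased).
study_table <- function() confusion_table(tp = 112, fp = 71, fn = 11, tn = 657)

test_that("confusion tables equal an exhaustive per-subject tally", {
  ct <- confusion_from_scores(c(28, 26), c(TRUE, FALSE), 27)
  expect_equal(ct[c("tp", "fp", "fn", "tn")],
               list(tp = 1, fp = 0, fn = 0, tn = 1))
  # the boundary value is screen-positive under the >= rule
  ct2 <- confusion_from_scores(c(27, 27), c(TRUE, FALSE), 27)
  expect_equal(ct2$tp, 1); expect_equal(ct2$fp, 1)

  set.seed(101)
  for (i in 1:50) {
    n <- sample(4:20, 1)
    marker <- round(runif(n, 20, 30), 1)
    ref <- runif(n) < 0.5
    if (!any(ref) || all(ref)) next
    cutoff <- sample(marker, 1)
    ct <- confusion_from_scores(marker, ref, cutoff)
    # brute-force subject-by-subject tally
    tally <- c(tp = 0, fp = 0, fn = 0, tn = 0)
    for (j in seq_len(n)) {
      cell <- if (marker[j] >= cutoff && ref[j]) "tp"
      else if (marker[j] >= cutoff) "fp"
      else if (ref[j]) "fn" else "tn"
      tally[cell] <- tally[cell] + 1
    }
    expect_equal(unlist(ct[c("tp", "fp", "fn", "tn")]), tally)
  }
  expect_error(confusion_from_scores(1:3, c(TRUE, FALSE), 2))
  expect_error(confusion_from_scores(1:3, c(TRUE, TRUE, TRUE), 2))
})

test_that("the metric panel reproduces the study table at printed rounding", {
  sm <- summarize_confusion(study_table())
  expect_equal(round(100 * sm$sensitivity$point, 1), 91.1)
  # counts give 90.247%: one rounding unit below the printed 90.3
  expect_equal(round(100 * sm$specificity$point, 1), 90.2)
  expect_lt(abs(100 * sm$specificity$point - 90.3), 0.06)
  # counts give 61.2%, not the printed 61.7 (documented discrepancy)
  expect_equal(round(100 * sm$ppv$point, 1), 61.2)
  # counts give NPV 98.35%, one rounding unit above the printed 98.3
  expect_equal(round(100 * sm$npv$point, 1), 98.4)
  expect_lt(abs(100 * sm$npv$point - 98.3), 0.06)
  expect_equal(round(100 * sm$accuracy$point, 1), 90.4)
  expect_equal(round(sm$youden_j$point, 2), 0.81)
  expect_equal(round(sm$lr_pos$point, 1), 9.3)
  expect_equal(round(sm$lr_neg$point, 2), 0.10)
})

test_that("panel metrics equal direct evaluation of their defining formulas", {
  expect_equal(
    {
      sm <- summarize_confusion(confusion_table(tp = 10, fp = 0, fn = 0, tn = 10))
      c(sm$sensitivity$point, sm$specificity$point, sm$ppv$point,
        sm$npv$point, sm$accuracy$point, sm$youden_j$point, sm$lr_neg$point)
    },
    c(1, 1, 1, 1, 1, 1, 0))
  set.seed(7)
  for (i in 1:40) {
    tp <- sample(1:50, 1); fp <- sample(1:50, 1)
    fn <- sample(1:50, 1); tn <- sample(1:50, 1)
    sm <- summarize_confusion(confusion_table(tp = tp, fp = fp, fn = fn, tn = tn))
    sens <- tp / (tp + fn); spec <- tn / (tn + fp)
    expect_equal(sm$sensitivity$point, sens)
    expect_equal(sm$specificity$point, spec)
    expect_equal(sm$ppv$point, tp / (tp + fp))
    expect_equal(sm$npv$point, tn / (tn + fn))
    expect_equal(sm$accuracy$point, (tp + tn) / (tp + fp + fn + tn))
    expect_equal(sm$youden_j$point, sens + spec - 1)
    expect_equal(sm$lr_pos$point, sens / (1 - spec))
    expect_equal(sm$lr_neg$point, (1 - sens) / spec)
    # accuracy decomposes through prevalence
    prev <- (tp + fn) / (tp + fp + fn + tn)
    expect_equal(sm$accuracy$point, prev * sens + (1 - prev) * spec)
  }
})

test_that("zero-denominator metrics are reported as undefined, others computed", {
  sm <- summarize_confusion(confusion_table(tp = 0, fp = 0, fn = 5, tn = 5))
  expect_true(is.na(sm$ppv$point))          # no screen-positives
  expect_equal(sm$specificity$point, 1)     # still defined
  expect_equal(sm$sensitivity$point, 0)
})

test_that("exact binomial interval matches the study CI and the tail equations", {
  ci <- proportion_ci_exact(112, 123)
  expect_equal(round(100 * ci$lower, 1), 84.6)
  expect_equal(round(100 * ci$upper, 1), 95.5)
  expect_equal(proportion_ci_exact(123, 123)$upper, 1)
  expect_equal(proportion_ci_exact(0, 50)$lower, 0)
  # cross-check against the base exact test
  bt <- binom.test(112, 123)$conf.int
  expect_equal(c(ci$lower, ci$upper), as.numeric(bt), tolerance = 1e-10)
  # root-finding oracle: bounds solve the exact binomial tail equations
  # P(X <= x | upper) = alpha/2 and P(X >= x | lower) = alpha/2
  x <- 7; n <- 19; ci2 <- proportion_ci_exact(x, n)
  expect_equal(pbinom(x, n, ci2$upper), 0.025, tolerance = 1e-8)
  expect_equal(pbinom(x - 1, n, ci2$lower, lower.tail = FALSE), 0.025,
               tolerance = 1e-8)
  # confirmed by a fine grid search over p
  grid <- seq(1e-4, 1 - 1e-4, by = 1e-4)
  up <- grid[which.min(abs(pbinom(x, n, grid) - 0.025))]
  lo <- grid[which.min(abs(pbinom(x - 1, n, grid, lower.tail = FALSE) - 0.025))]
  expect_equal(ci2$upper, up, tolerance = 1e-3)
  expect_equal(ci2$lower, lo, tolerance = 1e-3)
  expect_error(proportion_ci_exact(5, 4))
})

test_that("Clopper-Pearson contains the point and widens as trials shrink", {
  for (p in c(0.2, 0.5, 0.9)) {
    widths <- sapply(c(200, 50, 10), function(n) {
      x <- round(p * n)
      ci <- proportion_ci_exact(x, n)
      expect_gte(x / n, ci$lower); expect_lte(x / n, ci$upper)
      ci$upper - ci$lower
    })
    expect_true(all(diff(widths) > 0))
  }
})

test_that("log-method likelihood-ratio intervals reproduce the study CIs", {
  pos <- likelihood_ratio_ci(study_table(), "positive")
  expect_equal(round(pos$lower, 1), 7.4)
  expect_equal(round(pos$upper, 1), 11.7)
  neg <- likelihood_ratio_ci(study_table(), "negative")
  expect_equal(round(neg$lower, 1), 0.1)
  expect_equal(round(neg$upper, 1), 0.2)
  # symmetric table: swapping disease labels swaps LR+ <-> 1/LR-
  sym <- confusion_table(tp = 30, fp = 12, fn = 12, tn = 30)
  p1 <- likelihood_ratio_ci(sym, "positive")
  n1 <- likelihood_ratio_ci(sym, "negative")
  expect_equal(p1$point, 1 / n1$point)
  expect_equal(p1$lower, 1 / n1$upper, tolerance = 1e-10)
  # zero cell -> explicitly undefined interval with a note
  z <- likelihood_ratio_ci(confusion_table(tp = 10, fp = 0, fn = 2, tn = 20),
                           "positive")
  expect_true(is.na(z$lower))
  expect_match(attr(z, "note"), "zero cell")
})

test_that("sensitivity and specificity respond monotonically to the cutoff", {
  set.seed(21)
  marker <- round(rnorm(60, 25, 3), 1)
  ref <- runif(60) < plogis(marker - 25)
  cuts <- sort(unique(marker))
  sens <- spec <- numeric(length(cuts))
  for (i in seq_along(cuts)) {
    sm <- summarize_confusion(confusion_from_scores(marker, ref, cuts[i]))
    sens[i] <- sm$sensitivity$point; spec[i] <- sm$specificity$point
  }
  expect_true(all(diff(sens) <= 0))
  expect_true(all(diff(spec) >= 0))
  # extreme cutoffs: everyone screen-positive / screen-negative
  lo <- summarize_confusion(confusion_from_scores(marker, ref, min(marker)))
  expect_equal(lo$sensitivity$point, 1)
  hi <- summarize_confusion(confusion_from_scores(marker, ref, max(marker) + 1))
  expect_equal(hi$specificity$point, 1)
  expect_equal(hi$sensitivity$point, 0)
})
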