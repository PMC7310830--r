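# brute-force AUC: average pairwise comparison over all (pos, neg) pairs
pairwise_auc <- function(marker, reference) {
  pos <- marker[reference]; neg <- marker[!reference]
  mean(outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b)))
}

test_that("empirical AUC equals exhaustive pairwise enumeration", {
  expect_equal(empirical_auc(c(3, 4, 1, 2), c(TRUE, TRUE, FALSE, FALSE)), 1)
  expect_equal(empirical_auc(c(1, 2, 1, 2), c(TRUE, TRUE, FALSE, FALSE)), 0.5)
  # hand enumeration: pairs (2,1)+, (2,3)-, (3,1)+, (3,3) tie -> 2.5/4
  expect_equal(empirical_auc(c(2, 3, 1, 3), c(TRUE, TRUE, FALSE, FALSE)), 0.625)
  set.seed(31)
  for (i in 1:60) {
    n <- sample(4:25, 1)
    marker <- sample(round(runif(n, 0, 10), 1), n, replace = TRUE)
    ref <- runif(n) < 0.5
    if (!any(ref) || all(ref)) next
    expect_equal(empirical_auc(marker, ref), pairwise_auc(marker, ref),
                 tolerance = 1e-12)
  }
  expect_error(empirical_auc(1:3, c(TRUE, TRUE, TRUE)))
})

test_that("AUC equals the trapezoidal area under its own ROC curve", {
  set.seed(32)
  for (i in 1:30) {
    n <- sample(6:40, 1)
    marker <- round(rnorm(n, 25, 3), 1)
    ref <- runif(n) < 0.4
    if (!any(ref) || all(ref)) next
    roc <- roc_curve(marker, ref)
    expect_equal(empirical_auc(marker, ref), muacscreen:::trapezoid_auc(roc),
                 tolerance = 1e-12)
    # curve invariants
    expect_true(all(roc$fpr >= 0 & roc$fpr <= 1))
    expect_true(all(diff(roc$tpr) >= 0))  # rows ordered by decreasing cutoff
    expect_true(all(diff(roc$fpr) >= 0))
    expect_equal(c(roc$fpr[1], roc$tpr[1]), c(0, 0))
    expect_equal(c(roc$fpr[nrow(roc)], roc$tpr[nrow(roc)]), c(1, 1))
  }
})

test_that("AUC is rank-invariant and label-swap maps it to its complement", {
  set.seed(33)
  marker <- rnorm(40, 25, 3)
  ref <- runif(40) < plogis(marker - 25)
  if (!any(ref) || all(ref)) ref[1:2] <- c(TRUE, FALSE)
  a <- empirical_auc(marker, ref)
  expect_equal(empirical_auc(exp(marker / 5), ref), a, tolerance = 1e-12)
  expect_equal(empirical_auc(qlogis(plogis(marker - 25)), ref), a,
               tolerance = 1e-12)
  expect_equal(empirical_auc(marker, !ref), 1 - a, tolerance = 1e-12)
})

test_that("DeLong variance matches brute-force structural components and pROC", {
  set.seed(34)
  marker <- c(1.2, 3.4, 2.2, 5.1, 0.7, 4.4, 3.6, 3.3, 1.9, 4.0)
  ref <- c(FALSE, TRUE, FALSE, TRUE, FALSE, TRUE, FALSE, TRUE, FALSE, TRUE)
  cp <- muacscreen:::delong_components(marker, ref)
  # brute force per-subject placement means
  pos <- marker[ref]; neg <- marker[!ref]
  psi <- function(a, b) (a > b) + 0.5 * (a == b)
  v10 <- sapply(pos, function(a) mean(psi(a, neg)))
  v01 <- sapply(neg, function(b) mean(psi(pos, b)))
  expect_equal(cp$v10, v10, tolerance = 1e-12)
  expect_equal(cp$v01, v01, tolerance = 1e-12)
  expect_equal(mean(v10), empirical_auc(marker, ref), tolerance = 1e-12)

  skip_if_not_installed("pROC")
  ci <- auc_ci(marker, ref)
  pci <- suppressMessages(as.numeric(
    pROC::ci.auc(pROC::roc(ref, marker, quiet = TRUE), method = "delong")))
  expect_equal(c(ci$lower, ci$point, ci$upper), pci, tolerance = 1e-9)
})

test_that("perfectly separated classes give a degenerate AUC interval", {
  expect_warning(
    ci <- auc_ci(c(30, 31, 20, 21), c(TRUE, TRUE, FALSE, FALSE)),
    "perfect separation")
  expect_equal(c(ci$point, ci$lower, ci$upper), c(1, 1, 1))
})

test_that("DeLong interval approximately covers the true AUC", {
  # binormal model: true AUC = pnorm(delta / sqrt(2))
  delta <- 1
  true_auc <- pnorm(delta / sqrt(2))
  set.seed(35)
  cover <- replicate(400, {
    marker <- c(rnorm(20, delta), rnorm(20))
    ref <- rep(c(TRUE, FALSE), each = 20)
    ci <- auc_ci(marker, ref)
    ci$lower <= true_auc && true_auc <= ci$upper
  })
  # 95% nominal; allow Monte-Carlo slack plus small-sample undercoverage
  expect_gt(mean(cover), 0.90)
  expect_lte(mean(cover), 1.0)
})

test_that("AUC bands follow the published ranges with closed upper boundaries", {
  expect_equal(band_auc(0.96), "excellent")
  expect_equal(band_auc(0.85), "good")
  expect_equal(band_auc(0.90), "excellent")
  expect_equal(band_auc(0.80), "good")
  expect_equal(band_auc(0.75), "fair")
  expect_equal(band_auc(0.65), "poor")
  expect_equal(band_auc(0.55), "fail")
  expect_warning(expect_equal(band_auc(0.3), "fail"), "worse than chance")
})

test_that("Youden cutoff equals exhaustive candidate search with smallest-cutoff ties", {
  yc <- optimal_cutoff_youden(c(28, 29, 30, 24, 25, 26, 28),
                              c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE))
  expect_equal(yc$cutoff, 28)
  expect_equal(yc$youden_j, 0.75)
  yc2 <- optimal_cutoff_youden(c(30, 31, 20, 21), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(yc2$cutoff, 30); expect_equal(yc2$youden_j, 1)

  set.seed(36)
  for (i in 1:40) {
    n <- sample(8:30, 1)
    marker <- round(rnorm(n, 25, 2), 1)
    ref <- runif(n) < plogis(marker - 25)
    if (!any(ref) || all(ref) || length(unique(marker)) < 2) next
    yc <- optimal_cutoff_youden(marker, ref)
    # brute force over every observed candidate cutoff
    js <- sapply(sort(unique(marker)), function(ct) {
      sm <- summarize_confusion(confusion_from_scores(marker, ref, ct))
      sm$youden_j$point
    })
    expect_equal(yc$youden_j, max(js), tolerance = 1e-12)
    best <- sort(unique(marker))[js >= max(js) - 1e-12]
    expect_equal(yc$cutoff, min(best))
    # J coincides with the maximal tpr - fpr over the returned curve
    expect_equal(yc$youden_j, max(yc$roc$tpr - yc$roc$fpr), tolerance = 1e-12)
    # and with the panel identity at the optimum
    expect_equal(yc$youden_j,
                 yc$summary$sensitivity$point + yc$summary$specificity$point - 1,
                 tolerance = 1e-12)
  }
  expect_error(optimal_cutoff_youden(rep(5, 6), rep(c(TRUE, FALSE), 3)),
               "identical")
})
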