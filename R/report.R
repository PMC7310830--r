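# Rendering and export of the pipeline report bundle.
# Presentation rounding follows the usual diagnostic-table conventions:
# one decimal for percentages, two for ratios and the Youden index. Raw
# precision is always retained in the CSV exports.

fmt_pct_ci <- function(est) {
  if (is.na(est$point)) return("undefined")
  sprintf("%.1f (%.1f-%.1f)", 100 * est$point, 100 * est$lower, 100 * est$upper)
}

fmt_ratio_ci <- function(est) {
  if (is.na(est$point)) return("undefined")
  if (is.na(est$lower)) return(sprintf("%.2f (CI undefined)", est$point))
  sprintf("%.2f (%.2f-%.2f)", est$point, est$lower, est$upper)
}

#' Render a pipeline report as text lines
#'
#' @param report A [run_pipeline()] result.
#' @return Character vector of report lines (deterministic for a
#'   deterministic report).
#' @export
render_report <- function(report) {
  stopifnot(inherits(report, "muac_report"))
  x <- report
  ln <- character(0)
  add <- function(...) ln <<- c(ln, sprintf(...))

  add("=== MUAC screening accuracy report ===")
  add("")
  add("-- Participant flow --")
  fl <- x$flow
  add("approached %d | absent %d | refused %d | missing measurements %d | analysed %d",
      fl$approached, fl$excluded_absent, fl$excluded_refused,
      fl$missing_excluded, fl$analysed)
  add("")
  add("-- Descriptives: mean (SD) --")
  for (s in names(x$descriptives)) {
    d <- x$descriptives[[s]]
    add("%-6s n=%d  age %.1f (%.1f) y | height %.1f (%.1f) cm | weight %.1f (%.1f) kg | BMI Z %.2f (%.2f) | MUAC %.1f (%.1f) cm",
        s, d$n, d$age["mean"], d$age["sd"], d$height["mean"], d$height["sd"],
        d$weight["mean"], d$weight["sd"], d$bmi_z["mean"], d$bmi_z["sd"],
        d$muac["mean"], d$muac["sd"])
  }
  add("")
  add("-- Prevalence (BMI Z reference) --")
  for (i in seq_len(nrow(x$prevalence))) {
    p <- x$prevalence[i, ]
    add("%-22s %d/%d = %.1f%% (%.1f-%.1f)", p$category, p$count, p$n,
        100 * p$proportion, 100 * p$lower, 100 * p$upper)
  }
  add("")
  add("-- Correlation (Spearman) --")
  cr <- x$correlation$muac_bmiz
  add("MUAC ~ BMI Z: rho %.2f (%.2f-%.2f), n=%d", cr$rho, cr$ci$lower,
      cr$ci$upper, cr$n)
  ca <- x$correlation$muac_age
  add("MUAC ~ age : rho %.2f (%.2f-%.2f), n=%d", ca$rho, ca$ci$lower,
      ca$ci$upper, ca$n)
  add("")
  add("-- Discrimination (AUC, DeLong CI) --")
  for (s in names(x$auc)) {
    a <- x$auc[[s]]
    add("%-6s AUC %.2f (%.2f-%.2f), band %s", s, a$auc, a$ci$lower,
        a$ci$upper, a$band)
  }
  o <- x$optimism
  add("bootstrap optimism %.4f over %d resamples (seed %s); corrected AUC %.2f",
      o$mean_optimism, o$n_boot, format(o$seed), o$corrected_auc)
  add("")
  add("-- Calibration (MUAC logistic model) --")
  cal <- x$calibration
  add("Hosmer-Lemeshow chi2 %.2f on %d df, p = %.3f; slope %.2f, intercept %.2f",
      cal$statistic, cal$df, cal$p_value, cal$slope, cal$intercept)
  add("")
  add("-- Youden-optimal cutoffs and diagnostic panel --")
  add("%-6s %9s %6s %18s %18s %18s %18s %14s %14s %10s %6s", "strat",
      "cutoff", "J", "sens % (CI)", "spec % (CI)", "PPV % (CI)",
      "NPV % (CI)", "LR+ (CI)", "LR- (CI)", "correct %", "n")
  for (s in names(x$cutoffs)) {
    yc <- x$cutoffs[[s]]
    sm <- yc$summary
    add("%-6s >= %6.2f %6.2f %18s %18s %18s %18s %14s %14s %10.1f %6d",
        s, yc$cutoff, yc$youden_j, fmt_pct_ci(sm$sensitivity),
        fmt_pct_ci(sm$specificity), fmt_pct_ci(sm$ppv), fmt_pct_ci(sm$npv),
        fmt_ratio_ci(sm$lr_pos), fmt_ratio_ci(sm$lr_neg),
        100 * sm$accuracy$point, sm$n)
  }
  add("")
  add("-- Pooled confusion table (rule: %s cutoff) --", x$config$pooled_rule)
  ct <- x$pooled_confusion
  add("            reference+  reference-")
  add("screen+   %9d  %9d", ct$tp, ct$fp)
  add("screen-   %9d  %9d", ct$fn, ct$tn)
  ln
}

#' Write the report bundle to an output directory
#'
#' Writes `report.txt` (the rendered report), `metrics.csv` (the
#' per-stratum diagnostic panel at full precision), `roc.csv` (pooled ROC
#' operating points), `calibration.csv` (calibration bins) and `flow.json`.
#'
#' @param report A [run_pipeline()] result.
#' @param out_dir Output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
write_report_bundle <- function(report, out_dir) {
  stopifnot(inherits(report, "muac_report"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(out_dir, c("report.txt", "metrics.csv", "roc.csv",
                                "calibration.csv", "flow.json"))
  writeLines(render_report(report), paths[1])

  metrics <- do.call(rbind, lapply(names(report$cutoffs), function(s) {
    df <- as.data.frame(report$cutoffs[[s]]$summary)
    cbind(stratum = s, cutoff = report$cutoffs[[s]]$cutoff, df)
  }))
  utils::write.csv(metrics, paths[2], row.names = FALSE, quote = FALSE)
  utils::write.csv(report$cutoffs$total$roc, paths[3], row.names = FALSE,
                   quote = FALSE)
  utils::write.csv(report$calibration$bins, paths[4], row.names = FALSE,
                   quote = FALSE)
  jsonlite::write_json(unclass(report$flow), paths[5], auto_unbox = TRUE)
  invisible(paths)
}
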