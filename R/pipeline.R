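#' Pipeline configuration
#'
#' @param seed RNG seed used by every stochastic step (bootstrap).
#' @param n_boot Bootstrap resamples for the optimism correction.
#' @param level Confidence level for every interval.
#' @param n_bins Calibration bins (Hosmer-Lemeshow groups).
#' @param repeat_threshold MUAC replicate tolerance, cm.
#' @param pooled_rule How the pooled (Table-2 style) confusion table is
#'   built: `"pooled"` dichotomizes everyone at the pooled Youden cutoff,
#'   `"sex_specific"` applies each sex its own optimal cutoff.
#' @param interpolate Interpolate LMS parameters in age.
#' @return Object of class `pipeline_config` (a validated list).
#' @export
pipeline_config <- function(seed = 20200623, n_boot = 1000, level = 0.95,
                            n_bins = 10, repeat_threshold = 0.5,
                            pooled_rule = c("pooled", "sex_specific"),
                            interpolate = FALSE) {
  pooled_rule <- match.arg(pooled_rule)
  stopifnot(n_boot >= 1, level > 0, level < 1, n_bins >= 2,
            repeat_threshold > 0)
  structure(list(seed = seed, n_boot = n_boot, level = level,
                 n_bins = n_bins, repeat_threshold = repeat_threshold,
                 pooled_rule = pooled_rule, interpolate = interpolate),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a JSON or YAML file
#'
#' Recognized keys are the arguments of [pipeline_config()]; unknown keys
#' are an error.
#'
#' @param path Config file path.
#' @return A [pipeline_config()].
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)   # YAML is a JSON superset
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(cfg), known)
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  do.call(pipeline_config, cfg)
}

#' Participant flow counts
#'
#' @param approached Subjects approached.
#' @param excluded_absent,excluded_refused Pre-enrolment exclusions.
#' @param missing_excluded Enrolled records excluded for missing
#'   measurements.
#' @return Object of class `flow_counts` with the implied `analysed` count.
#' @export
flow_counts <- function(approached, excluded_absent = 0, excluded_refused = 0,
                        missing_excluded = 0) {
  analysed <- approached - excluded_absent - excluded_refused - missing_excluded
  if (analysed < 0) stop("exclusions exceed the approached count")
  structure(list(approached = approached, excluded_absent = excluded_absent,
                 excluded_refused = excluded_refused,
                 missing_excluded = missing_excluded, analysed = analysed),
            class = "flow_counts")
}

#' Prevalence of weight-status categories with exact intervals
#'
#' Counts and Clopper-Pearson intervals for overweight-only
#' (1 < BMI Z <= 2), obesity (BMI Z > 2) and the combined overweight
#' including obesity (BMI Z > 1).
#'
#' @param bmi_z BMI-for-age Z-scores of the analysed records.
#' @param level Confidence level.
#' @return Data frame with columns `category`, `count`, `n`, `proportion`,
#'   `lower`, `upper`.
#' @export
estimate_prevalence <- function(bmi_z, level = 0.95) {
  bmi_z <- bmi_z[!is.na(bmi_z)]
  n <- length(bmi_z)
  if (n == 0L) stop("no analysed records")
  counts <- c(overweight_only = sum(is_overweight(bmi_z) & !is_obese(bmi_z)),
              obese = sum(is_obese(bmi_z)),
              overweight_incl_obese = sum(is_overweight(bmi_z)))
  rows <- lapply(names(counts), function(cat) {
    ci <- proportion_ci_exact(counts[[cat]], n, level)
    data.frame(category = cat, count = counts[[cat]], n = n,
               proportion = ci$point, lower = ci$lower, upper = ci$upper,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Design-stage sample size for a diagnostic accuracy study
#'
#' Buderer-type arms: `n_sens = ceil(z^2 sens (1-sens) / (d^2 prev))` and
#' `n_spec = ceil(z^2 spec (1-spec) / (d^2 (1-prev)))` with margin of error
#' `d`; the final size inflates the larger arm by the design effect and the
#' anticipated non-response.
#'
#' @param sens,spec Anticipated sensitivity and specificity, in (0, 1).
#' @param prevalence Anticipated disease prevalence, in (0, 1).
#' @param margin Absolute margin of error (default 0.05).
#' @param design_effect Multiplier for a clustered design (default 1).
#' @param nonresponse Anticipated non-response fraction (default 0).
#' @param level Confidence level behind `z`.
#' @return List with `n_sens`, `n_spec`, `final`.
#' @export
sample_size_diagnostic <- function(sens, spec, prevalence, margin = 0.05,
                                   design_effect = 1, nonresponse = 0,
                                   level = 0.95) {
  for (p in c(sens, spec, prevalence)) {
    if (!is.numeric(p) || p <= 0 || p >= 1) {
      stop("sens, spec and prevalence must lie strictly in (0, 1)")
    }
  }
  stopifnot(margin > 0, design_effect >= 1, nonresponse >= 0, nonresponse < 1)
  z <- stats::qnorm(1 - (1 - level) / 2)
  n_sens <- ceiling(z^2 * sens * (1 - sens) / (margin^2 * prevalence))
  n_spec <- ceiling(z^2 * spec * (1 - spec) / (margin^2 * (1 - prevalence)))
  final <- ceiling(max(n_sens, n_spec) * design_effect * (1 + nonresponse))
  list(n_sens = n_sens, n_spec = n_spec, final = final)
}

# internal: mean (sd) descriptives for one stratum
describe_stratum <- function(df) {
  vars <- c(age = "age_years", height = "height_cm", weight = "weight_kg",
            bmi_z = "bmi_z", muac = "muac_cm")
  out <- lapply(vars, function(v) c(mean = mean(df[[v]]), sd = stats::sd(df[[v]])))
  c(list(n = nrow(df)), out)
}

#' Run the full screening-accuracy pipeline
#'
#' End-to-end analysis of a subject table: replicate averaging and BMI-Z
#' derivation, missing-record exclusion, descriptives, Spearman correlations
#' (MUAC-BMI Z, MUAC-age), ROC/AUC with DeLong intervals overall and per
#' sex, bootstrap optimism correction of the overall AUC, Hosmer-Lemeshow
#' calibration of the MUAC logistic model, Youden-optimal cutoffs with the
#' full diagnostic panel per stratum, the pooled confusion table, prevalence
#' estimates, and participant-flow accounting. Deterministic given the
#' config seed.
#'
#' @param subjects Subject data frame or path to a subject CSV.
#' @param config A [pipeline_config()].
#' @param lms Optional LMS reference table (path or data frame); needed only
#'   when the input has no precomputed `bmi_z` column.
#' @param flow Optional named list/vector with `approached`,
#'   `excluded_absent`, `excluded_refused` for the flow block; defaults
#'   treat the input table as everyone approached.
#' @return Object of class `muac_report`: a list of all result blocks.
#' @export
run_pipeline <- function(subjects, config = pipeline_config(), lms = NULL,
                         flow = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.character(subjects)) subjects <- read_subjects(subjects)
  if (is.character(lms)) lms <- read_lms(lms)

  prepared <- prepare_subjects(subjects, lms = lms,
                               repeat_threshold = config$repeat_threshold,
                               interpolate = config$interpolate)
  analysed <- prepared[!prepared$excluded_missing & !is.na(prepared$bmi_z), ]
  n_missing <- sum(prepared$excluded_missing)
  if (nrow(analysed) == 0L) stop("no analysable records after exclusions")

  strata <- list(total = analysed,
                 male = analysed[analysed$sex == "male", ],
                 female = analysed[analysed$sex == "female", ])
  for (s in c("male", "female")) {
    st <- strata[[s]]
    if (nrow(st) > 0L &&
        (all(st$status_overweight) || !any(st$status_overweight))) {
      stop("one-class stratum: ", s,
           " has no reference-", if (all(st$status_overweight)) "negative" else "positive",
           " subjects")
    }
  }

  level <- config$level
  descriptives <- lapply(strata, describe_stratum)
  correlation <- list(
    muac_bmiz = spearman_rho(analysed$muac_cm, analysed$bmi_z, level),
    muac_age = spearman_rho(analysed$muac_cm, analysed$age_years, level))

  auc <- lapply(strata, function(st)
    auc_result(st$muac_cm, st$status_overweight, level))
  optimism <- bootstrap_optimism(analysed$muac_cm, analysed$status_overweight,
                                 n_boot = config$n_boot, seed = config$seed)
  fit <- fit_logistic_univariable(analysed$muac_cm, analysed$status_overweight)
  calibration <- calibration_assess(fit, n_bins = config$n_bins)

  cutoffs <- lapply(strata, function(st)
    optimal_cutoff_youden(st$muac_cm, st$status_overweight, level))

  if (config$pooled_rule == "pooled") {
    pooled_ct <- confusion_from_scores(analysed$muac_cm,
                                       analysed$status_overweight,
                                       cutoffs$total$cutoff)
  } else {
    screen_pos <- ifelse(analysed$sex == "male",
                         analysed$muac_cm >= cutoffs$male$cutoff,
                         analysed$muac_cm >= cutoffs$female$cutoff)
    ref <- analysed$status_overweight
    pooled_ct <- confusion_table(tp = sum(screen_pos & ref),
                                 fp = sum(screen_pos & !ref),
                                 fn = sum(!screen_pos & ref),
                                 tn = sum(!screen_pos & !ref))
  }

  prevalence <- estimate_prevalence(analysed$bmi_z, level)

  fl <- flow_counts(
    approached = if (!is.null(flow$approached)) flow$approached else nrow(subjects),
    excluded_absent = if (!is.null(flow$excluded_absent)) flow$excluded_absent else 0,
    excluded_refused = if (!is.null(flow$excluded_refused)) flow$excluded_refused else 0,
    missing_excluded = n_missing)
  enrolled <- fl$approached - fl$excluded_absent - fl$excluded_refused
  if (enrolled != nrow(subjects)) {
    stop("flow counts inconsistent with the input table: approached - ",
         "pre-enrolment exclusions must equal the number of records")
  }

  structure(
    list(descriptives = descriptives, correlation = correlation, auc = auc,
         optimism = optimism, logistic_fit = fit, calibration = calibration,
         cutoffs = cutoffs, pooled_confusion = pooled_ct,
         prevalence = prevalence, flow = fl, config = config,
         analysed = analysed),
    class = "muac_report"
  )
}

#' @export
print.muac_report <- function(x, ...) {
  cat(render_report(x), sep = "\n")
  invisible(x)
}
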