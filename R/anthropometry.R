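#' Average replicate anthropometric measurements
#'
#' Field anthropometry protocols take each measurement twice and analyse the
#' average. When the two readings disagree by more than a tolerance (0.5 cm
#' for MUAC), the measurement is repeated and the average of the repeat pair
#' is used instead.
#'
#' @param first,second Numeric vectors of paired replicate readings (same
#'   unit, strictly positive).
#' @param repeat_first,repeat_second Optional repeat readings used when the
#'   original pair disagrees beyond `repeat_threshold`; `NA` where no repeat
#'   was taken.
#' @param repeat_threshold Maximum tolerated absolute difference between the
#'   two original readings, in the measurement unit. Default 0.5 (cm, the
#'   MUAC protocol tolerance).
#' @param id Optional subject labels used in error messages.
#' @return Numeric vector of per-subject averages at full input precision.
#'   Subjects whose original pair disagrees beyond the threshold and who have
#'   no repeat pair raise an error identifying them.
#' @examples
#' average_replicates(27.7, 27.8)                       # 27.75
#' average_replicates(25.0, 25.6, 25.2, 25.3)           # repeat rule: 25.25
#' @export
average_replicates <- function(first, second, repeat_first = NULL,
                               repeat_second = NULL, repeat_threshold = 0.5,
                               id = NULL) {
  assert_positive(first, "first")
  assert_positive(second, "second")
  stopifnot(length(first) == length(second))
  if (!is.numeric(repeat_threshold) || length(repeat_threshold) != 1L ||
      repeat_threshold <= 0) {
    stop("'repeat_threshold' must be a single positive number")
  }
  n <- length(first)
  if (is.null(repeat_first)) repeat_first <- rep(NA_real_, n)
  if (is.null(repeat_second)) repeat_second <- rep(NA_real_, n)
  if (is.null(id)) id <- seq_len(n)

  out <- (first + second) / 2
  disagree <- abs(first - second) > repeat_threshold
  has_repeat <- !is.na(repeat_first) & !is.na(repeat_second)

  missing_repeat <- disagree & !has_repeat
  if (any(missing_repeat)) {
    stop(sprintf(
      "replicate difference exceeds %g but no repeat pair recorded for subject(s): %s",
      repeat_threshold, paste(id[missing_repeat], collapse = ", ")),
      call. = FALSE)
  }
  use_rep <- disagree & has_repeat
  if (any(use_rep)) {
    assert_positive(repeat_first[use_rep], "repeat_first")
    assert_positive(repeat_second[use_rep], "repeat_second")
    out[use_rep] <- (repeat_first[use_rep] + repeat_second[use_rep]) / 2
  }
  out
}

#' Body mass index
#'
#' @param weight_kg Weight in kilograms.
#' @param height_cm Height in centimetres.
#' @return BMI in kg/m^2.
#' @examples
#' compute_bmi(56.6, 168.7)
#' @export
compute_bmi <- function(weight_kg, height_cm) {
  assert_positive(weight_kg, "weight_kg")
  assert_positive(height_cm, "height_cm")
  weight_kg / (height_cm / 100)^2
}

#' Technical error of measurement
#'
#' TEM over replicate pairs, sqrt(sum(d^2) / (2 n)) with d the within-pair
#' difference; the standard measurer-standardization statistic.
#'
#' @param first,second Numeric vectors of paired replicate readings.
#' @return TEM in the unit of the readings.
#' @export
technical_error_of_measurement <- function(first, second) {
  stopifnot(length(first) == length(second))
  if (length(first) < 1L) stop("at least one replicate pair is required")
  if (anyNA(first) || anyNA(second)) stop("replicate pairs must be complete")
  d <- first - second
  sqrt(sum(d^2) / (2 * length(d)))
}

#' BMI-for-age Z-score by the LMS method
#'
#' Converts a measurement to a Z-score against an LMS growth reference row
#' (Box-Cox power L, median M, coefficient of variation S):
#' `z = ((x/M)^L - 1) / (L * S)`, or `log(x/M)/S` when `L = 0`. Raw scores
#' beyond +/-3 are rescaled the way the WHO growth-standard software does:
#' above +3, `z = 3 + (x - sd3) / (sd3 - sd2)` where `sdK` is the measurement
#' at Z-score K; mirrored below -3. This keeps extreme values finite and
#' linear in the measurement.
#'
#' @param x Measurement (e.g. BMI in kg/m^2), strictly positive.
#' @param L,M,S LMS parameters (vectors recycled against `x`); `M > 0`,
#'   `S > 0`.
#' @return Z-score in standard-deviation units.
#' @examples
#' lms_zscore(24, L = -1.6, M = 20, S = 0.12)
#' @export
lms_zscore <- function(x, L, M, S) {
  assert_positive(x, "x")
  assert_positive(M, "M")
  assert_positive(S, "S")
  stopifnot(is.numeric(L))
  n <- length(x)
  L <- rep_len(L, n); M <- rep_len(M, n); S <- rep_len(S, n)

  z <- ifelse(L == 0, log(x / M) / S, ((x / M)^L - 1) / (L * S))

  hi <- z > 3
  if (any(hi)) {
    sd3 <- lms_centile(3, L[hi], M[hi], S[hi])
    sd2 <- lms_centile(2, L[hi], M[hi], S[hi])
    z[hi] <- 3 + (x[hi] - sd3) / (sd3 - sd2)
  }
  lo <- z < -3
  if (any(lo)) {
    sd3n <- lms_centile(-3, L[lo], M[lo], S[lo])
    sd2n <- lms_centile(-2, L[lo], M[lo], S[lo])
    z[lo] <- -3 + (x[lo] - sd3n) / (sd2n - sd3n)
  }
  z
}

# internal: measurement at a given (central-range) z for LMS parameters
lms_centile <- function(z, L, M, S) {
  ifelse(L == 0, M * exp(S * z), M * (1 + L * S * z)^(1 / L))
}

#' Inverse of the LMS Z-score
#'
#' Measurement value at a given Z-score, using the same restricted-tail
#' linearization beyond +/-3 as [lms_zscore()], so the two functions are
#' exact inverses over the whole real line.
#'
#' @param z Z-score in SD units.
#' @param L,M,S LMS parameters.
#' @return Measurement in the units of `M`.
#' @export
lms_inverse <- function(z, L, M, S) {
  assert_positive(M, "M")
  assert_positive(S, "S")
  n <- length(z)
  L <- rep_len(L, n); M <- rep_len(M, n); S <- rep_len(S, n)
  x <- ifelse(abs(z) <= 3, lms_centile(pmin(pmax(z, -3), 3), L, M, S), NA_real_)
  hi <- z > 3
  if (any(hi)) {
    sd3 <- lms_centile(3, L[hi], M[hi], S[hi])
    sd2 <- lms_centile(2, L[hi], M[hi], S[hi])
    x[hi] <- sd3 + (z[hi] - 3) * (sd3 - sd2)
  }
  lo <- z < -3
  if (any(lo)) {
    sd3n <- lms_centile(-3, L[lo], M[lo], S[lo])
    sd2n <- lms_centile(-2, L[lo], M[lo], S[lo])
    x[lo] <- sd3n + (z[lo] + 3) * (sd2n - sd3n)
  }
  x
}

#' Read an LMS growth-reference table
#'
#' Expects a delimited text file with header `sex,age_months,L,M,S`, sex coded
#' `male`/`female`, one row per (sex, age in months).
#'
#' @param path File path.
#' @return A validated data frame with those five columns.
#' @export
read_lms <- function(path) {
  lms <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("sex", "age_months", "L", "M", "S")
  if (!all(required %in% names(lms))) {
    stop("LMS table must have columns: ", paste(required, collapse = ", "))
  }
  lms$sex <- tolower(lms$sex)
  if (!all(lms$sex %in% c("male", "female"))) {
    stop("LMS sex must be coded male/female")
  }
  if (any(lms$M <= 0) || any(lms$S <= 0)) stop("LMS requires M > 0 and S > 0")
  if (anyDuplicated(lms[c("sex", "age_months")])) {
    stop("duplicate (sex, age_months) rows in LMS table")
  }
  lms[required]
}

#' Look up LMS parameters for subjects
#'
#' Matches each subject to the reference row of the same sex with the nearest
#' age in months (monthly reference tables; no interpolation by default).
#' With `interpolate = TRUE` the L, M and S parameters are interpolated
#' linearly in age between the two bracketing rows.
#'
#' @param lms LMS reference table as returned by [read_lms()].
#' @param sex Character vector, `male`/`female`.
#' @param age_years Numeric ages in years.
#' @param interpolate Interpolate parameters linearly in age instead of
#'   nearest-month matching.
#' @return Data frame with columns `L`, `M`, `S`, one row per subject.
#' @export
lms_lookup <- function(lms, sex, age_years, interpolate = FALSE) {
  stopifnot(length(sex) == length(age_years))
  age_months <- age_years * 12
  out <- data.frame(L = rep(NA_real_, length(sex)), M = NA_real_, S = NA_real_)
  for (s in unique(sex)) {
    ref <- lms[lms$sex == s, , drop = FALSE]
    if (nrow(ref) == 0L) stop("no LMS rows for sex: ", s)
    ref <- ref[order(ref$age_months), , drop = FALSE]
    idx <- which(sex == s)
    if (interpolate && nrow(ref) > 1L) {
      a <- pmin(pmax(age_months[idx], min(ref$age_months)), max(ref$age_months))
      for (p in c("L", "M", "S")) {
        out[[p]][idx] <- stats::approx(ref$age_months, ref[[p]], xout = a)$y
      }
    } else {
      nearest <- vapply(age_months[idx],
                        function(a) which.min(abs(ref$age_months - a)), 1L)
      out[idx, ] <- ref[nearest, c("L", "M", "S")]
    }
  }
  out
}

#' Classify weight status from a BMI-for-age Z-score
#'
#' WHO school-age convention: overweight (including obesity) is BMI Z strictly
#' above +1 SD; obesity is strictly above +2 SD (a subset of overweight).
#'
#' @param bmi_z Numeric Z-scores.
#' @return Ordered factor with levels `normal < overweight < obese`, where
#'   `overweight` here is the exclusive band 1 < z <= 2. Use
#'   [is_overweight()] / [is_obese()] for the inclusive binary statuses.
#' @export
classify_status <- function(bmi_z) {
  stopifnot(is.numeric(bmi_z), all(is.finite(bmi_z)))
  factor(ifelse(bmi_z > 2, "obese", ifelse(bmi_z > 1, "overweight", "normal")),
         levels = c("normal", "overweight", "obese"), ordered = TRUE)
}

#' @rdname classify_status
#' @return `is_overweight`: logical, BMI Z > +1 (overweight including
#'   obesity). `is_obese`: logical, BMI Z > +2.
#' @export
is_overweight <- function(bmi_z) bmi_z > 1

#' @rdname classify_status
#' @export
is_obese <- function(bmi_z) bmi_z > 2

#' Read / write the subject CSV dialect
#'
#' Subject tables are comma-separated with header
#' `id,sex,age_years,height1_cm,height2_cm,weight1_kg,weight2_kg,muac1_cm,muac2_cm`
#' and optional columns `muac_repeat1_cm,muac_repeat2_cm` (repeat MUAC pair
#' where the original readings disagreed) and `bmi_z` (precomputed
#' BMI-for-age Z-score). Sex is coded `male`/`female`; decimal point; UTF-8.
#'
#' @param path File path.
#' @return `read_subjects`: a data frame of raw subject records.
#' @export
read_subjects <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("id", "sex", "age_years", "height1_cm", "height2_cm",
                "weight1_kg", "weight2_kg", "muac1_cm", "muac2_cm")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("subject CSV missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  df$sex <- tolower(df$sex)
  if (!all(df$sex %in% c("male", "female"))) {
    stop("sex must be coded male/female")
  }
  df
}

#' @rdname read_subjects
#' @param subjects Data frame of subject records.
#' @export
write_subjects <- function(subjects, path) {
  utils::write.csv(subjects, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Derive analysis variables from raw subject records
#'
#' Averages the replicate height, weight and MUAC readings (applying the
#' repeat rule to MUAC), computes BMI, attaches the BMI-for-age Z-score
#' (from a precomputed `bmi_z` column when present, otherwise through the
#' LMS reference), and labels binary overweight/obesity status. Records with
#' a missing MUAC, weight or height are flagged for exclusion, not dropped.
#'
#' @param subjects Raw subject data frame ([read_subjects()]).
#' @param lms Optional LMS reference table; required when `subjects` has no
#'   `bmi_z` column.
#' @param repeat_threshold MUAC replicate tolerance in cm (default 0.5).
#' @param interpolate Passed to [lms_lookup()].
#' @return The input data frame with derived columns `height_cm`,
#'   `weight_kg`, `muac_cm`, `bmi`, `bmi_z`, `status` (3-level factor),
#'   `status_overweight`, `status_obese`, and logical `excluded_missing`.
#' @export
prepare_subjects <- function(subjects, lms = NULL, repeat_threshold = 0.5,
                             interpolate = FALSE) {
  df <- subjects
  measured <- c("height1_cm", "height2_cm", "weight1_kg", "weight2_kg",
                "muac1_cm", "muac2_cm")
  df$excluded_missing <- Reduce(`|`, lapply(df[measured], is.na))
  ok <- !df$excluded_missing

  df$height_cm <- df$weight_kg <- df$muac_cm <- NA_real_
  df$height_cm[ok] <- (df$height1_cm[ok] + df$height2_cm[ok]) / 2
  df$weight_kg[ok] <- (df$weight1_kg[ok] + df$weight2_kg[ok]) / 2
  rep1 <- if ("muac_repeat1_cm" %in% names(df)) df$muac_repeat1_cm[ok] else NULL
  rep2 <- if ("muac_repeat2_cm" %in% names(df)) df$muac_repeat2_cm[ok] else NULL
  df$muac_cm[ok] <- average_replicates(
    df$muac1_cm[ok], df$muac2_cm[ok], rep1, rep2,
    repeat_threshold = repeat_threshold, id = df$id[ok])

  df$bmi <- NA_real_
  df$bmi[ok] <- compute_bmi(df$weight_kg[ok], df$height_cm[ok])

  if (!("bmi_z" %in% names(df)) || all(is.na(df$bmi_z))) {
    if (is.null(lms)) {
      stop("no precomputed 'bmi_z' column: an LMS reference table is required")
    }
    df$bmi_z <- NA_real_
    par <- lms_lookup(lms, df$sex[ok], df$age_years[ok], interpolate)
    df$bmi_z[ok] <- lms_zscore(df$bmi[ok], par$L, par$M, par$S)
  }

  df$status <- factor(NA, levels = c("normal", "overweight", "obese"),
                      ordered = TRUE)
  good <- ok & !is.na(df$bmi_z)
  df$status[good] <- classify_status(df$bmi_z[good])
  df$status_overweight <- is_overweight(df$bmi_z)
  df$status_obese <- is_obese(df$bmi_z)
  df
}
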