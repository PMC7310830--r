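#' Synthetic cohort specification
#'
#' Parameters of the Gaussian-copula cohort generator. The defaults are the
#' study conditions this package is tested against: a two-sex adolescent
#' cohort of 456 males and 395 females with per-sex MUAC and BMI-Z marginals
#' (males 25.3 +/- 3.2 cm, -0.8 +/- 1.2 SD; females 25.7 +/- 3.4 cm,
#' -0.05 +/- 1.1 SD), age 16.7 +/- 1.1 years, per-sex height marginals
#' (168.7 +/- 6.8 / 157.0 +/- 6.3 cm), and a target Spearman(MUAC, BMI Z)
#' of 0.81. Overweight prevalence is emergent from the BMI-Z marginals, not
#' forced.
#'
#' @param n_male,n_female Stratum sizes.
#' @param muac_mean,muac_sd Named vectors `c(male = , female = )`, cm.
#' @param bmiz_mean,bmiz_sd Named vectors, SD units.
#' @param height_mean,height_sd Named vectors, cm.
#' @param age_mean,age_sd Years.
#' @param target_spearman Target Spearman correlation between MUAC and BMI Z.
#' @param replicate_error_sd Measurement noise SD added independently to each
#'   replicate reading, in instrument units (cm / kg), before rounding to the
#'   0.1 instrument precision.
#' @param seed RNG seed (required; the cohort is deterministic given it).
#' @return Object of class `cohort_spec` (a validated list).
#' @export
cohort_spec <- function(n_male = 456, n_female = 395,
                        muac_mean = c(male = 25.3, female = 25.7),
                        muac_sd = c(male = 3.2, female = 3.4),
                        bmiz_mean = c(male = -0.8, female = -0.05),
                        bmiz_sd = c(male = 1.2, female = 1.1),
                        height_mean = c(male = 168.7, female = 157.0),
                        height_sd = c(male = 6.8, female = 6.3),
                        age_mean = 16.7, age_sd = 1.1,
                        target_spearman = 0.81,
                        replicate_error_sd = 0.1,
                        seed) {
  if (missing(seed)) stop("'seed' is required: cohorts must be reproducible")
  sds <- c(muac_sd, bmiz_sd, height_sd, age_sd)
  if (any(sds <= 0)) stop("all standard deviations must be positive")
  if (abs(target_spearman) >= 1) stop("|target_spearman| must be < 1")
  if (replicate_error_sd < 0) stop("replicate_error_sd must be >= 0")
  stopifnot(n_male >= 1, n_female >= 1)
  for (v in list(muac_mean, muac_sd, bmiz_mean, bmiz_sd, height_mean, height_sd)) {
    if (!all(c("male", "female") %in% names(v))) {
      stop("per-sex parameters need named elements 'male' and 'female'")
    }
  }
  structure(
    list(n_male = n_male, n_female = n_female, muac_mean = muac_mean,
         muac_sd = muac_sd, bmiz_mean = bmiz_mean, bmiz_sd = bmiz_sd,
         height_mean = height_mean, height_sd = height_sd,
         age_mean = age_mean, age_sd = age_sd,
         target_spearman = target_spearman,
         replicate_error_sd = replicate_error_sd, seed = seed),
    class = "cohort_spec"
  )
}

#' Spearman-to-Pearson correlation map for a bivariate normal
#'
#' For a bivariate normal, the Spearman rank correlation `rs` and the Pearson
#' correlation `r` are related by `r = 2 sin(pi rs / 6)`. The generator uses
#' this to calibrate the copula so the *rank* correlation of the output hits
#' the target.
#'
#' @param rs Spearman correlation in `[-1, 1]`.
#' @return The Pearson correlation of the underlying bivariate normal.
#' @export
spearman_to_pearson <- function(rs) {
  stopifnot(all(abs(rs) <= 1))
  2 * sin(pi * rs / 6)
}

#' Synthetic LMS reference for BMI-for-age (ages 15-19)
#'
#' A small, entirely synthetic LMS table used by the cohort generator to
#' back-solve weight from a BMI Z-score. The medians rise gently with age and
#' the Box-Cox powers and coefficients of variation are plausible for
#' adolescent BMI, but these are NOT the WHO 2007 reference values, which
#' this package deliberately does not redistribute.
#'
#' @return Data frame with columns `sex`, `age_months`, `L`, `M`, `S`.
#' @export
synthetic_lms <- function() {
  ages <- c(180, 192, 204, 216, 228)  # 15-19 years, yearly rows
  data.frame(
    sex = rep(c("male", "female"), each = length(ages)),
    age_months = rep(ages, 2),
    L = c(rep(-1.9, length(ages)), rep(-1.7, length(ages))),
    M = c(19.8, 20.2, 20.6, 21.0, 21.3,   # male medians, kg/m^2
          20.3, 20.7, 21.1, 21.4, 21.6),  # female medians
    S = c(rep(0.125, length(ages)), rep(0.135, length(ages)))
  )
}

# internal: probabilists' Gauss-Hermite rule (nodes/weights w.r.t. the
# standard normal density) by Golub-Welsch
gauss_hermite_prob <- function(n) {
  if (n == 1) return(list(nodes = 0, weights = 1))
  off <- sqrt(seq_len(n - 1))
  J <- diag(0, n)
  J[cbind(seq_len(n - 1), seq_len(n - 1) + 1)] <- off
  J[cbind(seq_len(n - 1) + 1, seq_len(n - 1))] <- off
  e <- eigen(J, symmetric = TRUE)
  list(nodes = e$values, weights = e$vectors[1, ]^2)
}

#' Population Spearman correlation of the pooled two-sex cohort
#'
#' For a given latent (within-sex) Pearson correlation `rho`, computes the
#' Spearman correlation of (MUAC, BMI Z) over the pooled mixture of the two
#' sex strata, `12 E[F(X) G(Y)] - 3` with F, G the pooled marginal CDFs,
#' by Gauss-Hermite quadrature. Used to calibrate the copula: pooling strata
#' with different marginals attenuates the rank correlation below its
#' within-stratum value, and the study's reported correlation is a pooled
#' quantity.
#'
#' @param rho Latent within-sex Pearson correlation.
#' @param spec A [cohort_spec()].
#' @param n_nodes Quadrature nodes per dimension.
#' @return The pooled population Spearman correlation.
#' @export
pooled_spearman <- function(rho, spec, n_nodes = 40) {
  gh <- gauss_hermite_prob(n_nodes)
  w_sex <- c(male = spec$n_male, female = spec$n_female)
  w_sex <- w_sex / sum(w_sex)
  Fm <- function(x) sum(w_sex * stats::pnorm(x, spec$muac_mean, spec$muac_sd))
  Gz <- function(y) sum(w_sex * stats::pnorm(y, spec$bmiz_mean, spec$bmiz_sd))
  e <- 0
  for (s in c("male", "female")) {
    x <- spec$muac_mean[[s]] + spec$muac_sd[[s]] * gh$nodes
    fx <- vapply(x, Fm, 1.0)
    ymat <- spec$bmiz_mean[[s]] + spec$bmiz_sd[[s]] *
      (rho * outer(gh$nodes, rep(1, n_nodes)) +
         sqrt(1 - rho^2) * outer(rep(1, n_nodes), gh$nodes))
    gy <- matrix(vapply(ymat, Gz, 1.0), n_nodes, n_nodes)
    e <- e + w_sex[[s]] * sum(gh$weights * gy %*% gh$weights * fx)
  }
  12 * e - 3
}

# internal: latent Pearson rho giving the target *pooled* Spearman
calibrate_latent_rho <- function(spec) {
  target <- spec$target_spearman
  if (target == 0) return(0)
  f <- function(r) pooled_spearman(r, spec) - target
  stats::uniroot(f, c(-0.9999, 0.9999), tol = 1e-9)$root
}

#' Generate a synthetic subject cohort
#'
#' Per sex, draws (MUAC, BMI Z) from a bivariate normal with the spec
#' marginals; the shared latent Pearson correlation is calibrated (via
#' [pooled_spearman()] and the bivariate-normal rank-correlation map
#' [spearman_to_pearson()]) so that the *pooled* two-sex cohort attains the
#' target Spearman correlation, since pooling strata with different
#' marginals attenuates rank correlation and the study's correlation is a
#' pooled quantity. Draws age and height from their normal marginals;
#' back-solves BMI (and hence weight) from the BMI Z-score through the LMS
#' reference; and emits two replicate readings per measurement, each the true
#' value plus independent noise (`replicate_error_sd`), rounded to the 0.1
#' instrument precision. MUAC replicate pairs that disagree by more than
#' 0.5 cm receive a repeat pair, as the field protocol requires. The output
#' is deterministic given `spec$seed`.
#'
#' @param spec A [cohort_spec()].
#' @param lms LMS reference used to back-solve weight from BMI Z (default
#'   [synthetic_lms()]).
#' @param forced_prevalence Optional overall P(BMI Z > 1) to force by a
#'   common location shift of both sex strata (power experiments); default
#'   `NULL` leaves prevalence emergent from the marginals.
#' @return Data frame in the subject CSV dialect (see [read_subjects()]),
#'   including a precomputed `bmi_z` column.
#' @export
generate_cohort <- function(spec, lms = synthetic_lms(),
                            forced_prevalence = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  rho <- calibrate_latent_rho(spec)
  set.seed(spec$seed)

  shift <- 0
  if (!is.null(forced_prevalence)) {
    stopifnot(forced_prevalence > 0, forced_prevalence < 1)
    w <- c(spec$n_male, spec$n_female) / (spec$n_male + spec$n_female)
    tail_at <- function(d) {
      sum(w * stats::pnorm(1, mean = spec$bmiz_mean + d, sd = spec$bmiz_sd,
                           lower.tail = FALSE)) - forced_prevalence
    }
    shift <- stats::uniroot(tail_at, c(-20, 20), tol = 1e-10)$root
  }

  one_sex <- function(sex, n) {
    z1 <- stats::rnorm(n)
    z2 <- rho * z1 + sqrt(1 - rho^2) * stats::rnorm(n)
    muac_true <- spec$muac_mean[[sex]] + spec$muac_sd[[sex]] * z1
    bmi_z <- spec$bmiz_mean[[sex]] + shift + spec$bmiz_sd[[sex]] * z2
    age <- round(stats::rnorm(n, spec$age_mean, spec$age_sd), 1)
    height_true <- stats::rnorm(n, spec$height_mean[[sex]], spec$height_sd[[sex]])
    par <- lms_lookup(lms, rep(sex, n), age)
    bmi <- lms_inverse(bmi_z, par$L, par$M, par$S)
    weight_true <- bmi * (height_true / 100)^2

    noisy <- function(true) round(true + stats::rnorm(n, 0, spec$replicate_error_sd), 1)
    muac1 <- noisy(muac_true); muac2 <- noisy(muac_true)
    rep1 <- rep(NA_real_, n); rep2 <- rep(NA_real_, n)
    redo <- abs(muac1 - muac2) > 0.5
    if (any(redo)) {
      k <- sum(redo)
      rep1[redo] <- round(muac_true[redo] + stats::rnorm(k, 0, spec$replicate_error_sd), 1)
      rep2[redo] <- round(muac_true[redo] + stats::rnorm(k, 0, spec$replicate_error_sd), 1)
    }
    data.frame(
      sex = sex, age_years = age,
      height1_cm = noisy(height_true), height2_cm = noisy(height_true),
      weight1_kg = noisy(weight_true), weight2_kg = noisy(weight_true),
      muac1_cm = muac1, muac2_cm = muac2,
      muac_repeat1_cm = rep1, muac_repeat2_cm = rep2,
      bmi_z = bmi_z
    )
  }

  out <- rbind(one_sex("male", spec$n_male), one_sex("female", spec$n_female))
  out <- cbind(id = sprintf("S%04d", seq_len(nrow(out))), out)
  rownames(out) <- NULL
  out
}

#' Flag a random subset of records as incomplete
#'
#' Marks each record independently with probability `fraction` by blanking
#' one of its measurements (MUAC, weight or height, chosen at random), so a
#' downstream pipeline must exclude exactly those records. Deterministic
#' given `seed`.
#'
#' @param cohort Subject data frame.
#' @param fraction Per-record missingness probability in `[0, 1)`.
#' @param seed RNG seed.
#' @return The cohort with the selected measurements set to `NA`.
#' @export
inject_missingness <- function(cohort, fraction, seed) {
  if (!is.numeric(fraction) || fraction < 0 || fraction >= 1) {
    stop("'fraction' must be in [0, 1)")
  }
  if (fraction == 0) return(cohort)
  set.seed(seed)
  n <- nrow(cohort)
  hit <- stats::runif(n) < fraction
  field <- sample(c("muac1_cm", "weight1_kg", "height1_cm"), n, replace = TRUE)
  for (f in unique(field[hit])) {
    cohort[[f]][hit & field == f] <- NA_real_
  }
  cohort
}
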