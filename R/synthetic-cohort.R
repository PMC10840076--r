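#' Parameters for the synthetic anthropometric cohort generator
#'
#' Builds a validated parameter set for [generate_cohort()]. Defaults are
#' keyed to the sex-specific marginals of a large UK population cohort
#' (females: height 162 (6.3) cm, weight 71.4 (14.0) kg, body fat 36.6
#' (6.9)%; males: height 176 (6.8) cm, weight 86.0 (14.2) kg, body fat 25.3
#' (5.7)%), with a log-linear weight-height allometry of known ground-truth
#' exponent `p_true`, linear age trends in weight and fatness, and an
#' exponential (constant-baseline) proportional-hazards mortality process
#' with 12 years of administrative follow-up.
#'
#' The weight model is
#' `log(weight) = log(a) + p_true * log(height) + age_weight_slope * (age -
#' age_mean) + e`, `e ~ N(0, weight_log_sd^2)` independent of height. Unless
#' overridden, `weight_scale` (a) and `weight_log_sd` are calibrated in
#' closed form by lognormal moment matching so that the marginal weight
#' mean/SD hit `weight_mean_kg` / `weight_sd_kg`; likewise the residual SD
#' of the body-fat model is derived from `bf_sd_pct` after removing the age
#' and weight-residual contributions. See the package vignette for the
#' calibration algebra.
#'
#' @param sex `"F"` or `"M"`; selects the default marginal targets.
#' @param n Number of subjects (>= 2).
#' @param seed Integer seed; the generator is fully deterministic given the
#'   parameter set.
#' @param ... Named overrides for any parameter field (see Details).
#' @return An object of class `cohort_params` (a named list).
#' @export
cohort_params <- function(sex = c("F", "M"), n = 10000L, seed = 1L, ...) {
  sex <- match.arg(sex)
  base <- if (sex == "F") list(
    height_mean_cm = 162, height_sd_cm = 6.3,
    age_mean_y = 56.3, age_sd_y = 8.0, age_min_y = 40, age_max_y = 70,
    p_true = 1.4,
    weight_mean_kg = 71.4, weight_sd_kg = 14.0,
    age_weight_slope = 0.002,
    bf_mean_pct = 36.6, bf_sd_pct = 6.9,
    bf_age_slope = 0.1, bf_weight_resid_slope = 5,
    wc_intercept_cm = 57.8, wc_fm_slope = 1.0, wc_sd_cm = 7.4,
    hip_intercept_cm = 84.2, hip_fm_slope = 0.7, hip_sd_cm = 7.5,
    rsh_mean = 0.528, rsh_sd = 0.014,
    townsend_mean = -1.35, townsend_sd = 3.0,
    baseline_hazard = 0.0057, log_hr_age = 0.085, log_hr_index = 0.08,
    admin_censor_y = 12,
    ethnicity_freq = c(White = 201731, Asian = 4360, Black = 3546,
                       Other = 3433, Unknown = 831),
    alcohol_freq = c(Current = 193259, Never = 12425, Previous = 7710,
                     Unknown = 507),
    smoking_freq = c(Current = 19060, Never = 126939, Previous = 66880,
                     Unknown = 1022),
    education_freq = c(LessThanSecondary = 35842, Secondary = 41313,
                       Vocational = 12341, Higher = 54284, Unknown = 66094)
  ) else list(
    height_mean_cm = 176, height_sd_cm = 6.8,
    age_mean_y = 56.7, age_sd_y = 8.2, age_min_y = 40, age_max_y = 70,
    p_true = 1.8,
    weight_mean_kg = 86.0, weight_sd_kg = 14.2,
    age_weight_slope = 0.002,
    bf_mean_pct = 25.3, bf_sd_pct = 5.7,
    bf_age_slope = 0.1, bf_weight_resid_slope = 5,
    wc_intercept_cm = 74.7, wc_fm_slope = 1.0, wc_sd_cm = 7.6,
    hip_intercept_cm = 91.9, hip_fm_slope = 0.5, hip_sd_cm = 6.3,
    rsh_mean = 0.522, rsh_sd = 0.012,
    townsend_mean = -1.28, townsend_sd = 3.1,
    baseline_hazard = 0.010, log_hr_age = 0.085, log_hr_index = 0.08,
    admin_censor_y = 12,
    ethnicity_freq = c(White = 167621, Asian = 4434, Black = 2654,
                       Other = 2337, Unknown = 950),
    alcohol_freq = c(Current = 166585, Never = 4840, Previous = 6120,
                     Unknown = 451),
    smoking_freq = c(Current = 21892, Never = 87001, Previous = 68209,
                     Unknown = 894),
    education_freq = c(LessThanSecondary = 30186, Secondary = 23974,
                       Vocational = 8930, Higher = 51664, Unknown = 59739)
  )
  p <- utils::modifyList(base, list(...))
  p$sex <- sex
  p$n <- as.integer(n)
  p$seed <- as.integer(seed)

  # calibration inputs must be finite before the closed forms are evaluated
  for (v in c("p_true", "weight_mean_kg", "weight_sd_kg", "height_mean_cm",
              "height_sd_cm", "age_weight_slope", "age_sd_y"))
    if (!is.finite(p[[v]])) stop("non-finite parameter value(s): ", v)

  # closed-form lognormal calibration of the weight model (overridable)
  dots <- names(list(...))
  if (!"weight_scale" %in% dots || !"weight_log_sd" %in% dots) {
    cal <- calibrate_weight_model(
      p$weight_mean_kg, p$weight_sd_kg, p$p_true,
      p$height_mean_cm / 100, p$height_sd_cm / 100,
      p$age_weight_slope, p$age_sd_y)
    if (!"weight_scale" %in% dots) p$weight_scale <- cal$weight_scale
    if (!"weight_log_sd" %in% dots) p$weight_log_sd <- cal$weight_log_sd
  }
  if (!"bf_resid_sd" %in% dots) {
    v <- p$bf_sd_pct^2 - (p$bf_age_slope * p$age_sd_y)^2 -
      p$bf_weight_resid_slope^2
    if (v < 0)
      stop("body-fat SD target too small for the configured age and ",
           "weight-residual slopes")
    p$bf_resid_sd <- sqrt(v)
  }
  validate_cohort_params(p)
  structure(p, class = "cohort_params")
}

# Lognormal moment matching: choose log-scale intercept and residual SD so
# that the marginal weight mean/SD equal the configured targets given the
# height and age contributions (delta-method log-moments of height).
calibrate_weight_model <- function(mean_kg, sd_kg, p_true,
                                   h_mean_m, h_sd_m,
                                   age_slope, age_sd) {
  v_logh <- (h_sd_m / h_mean_m)^2
  mu_logh <- log(h_mean_m) - v_logh / 2
  v_logw <- log(1 + (sd_kg / mean_kg)^2)
  v_resid <- v_logw - p_true^2 * v_logh - (age_slope * age_sd)^2
  if (v_resid < 0)
    stop("weight SD target too small for the configured allometry slopes")
  mu_logw <- log(mean_kg) - v_logw / 2
  list(weight_scale = exp(mu_logw - p_true * mu_logh),
       weight_log_sd = sqrt(v_resid))
}

validate_cohort_params <- function(p) {
  num <- vapply(p[!vapply(p, is.character, logical(1L))],
                function(x) all(is.finite(unlist(x))), logical(1L))
  if (!all(num))
    stop("non-finite parameter value(s): ",
         paste(names(num)[!num], collapse = ", "))
  if (p$n < 2L) stop("'n' must be at least 2")
  pos_sds <- c("height_sd_cm", "age_sd_y", "rsh_sd", "townsend_sd",
               "wc_sd_cm", "hip_sd_cm")
  for (v in pos_sds) if (p[[v]] <= 0) stop("'", v, "' must be positive")
  if (p$weight_log_sd < 0) stop("'weight_log_sd' must be non-negative")
  if (p$bf_resid_sd < 0) stop("'bf_resid_sd' must be non-negative")
  if (p$bf_mean_pct <= 0 || p$bf_mean_pct >= 100)
    stop("'bf_mean_pct' must lie in (0, 100)")
  if (p$age_min_y >= p$age_max_y) stop("'age_min_y' must be below 'age_max_y'")
  if (p$admin_censor_y <= 0) stop("'admin_censor_y' must be positive")
  for (v in c("ethnicity_freq", "alcohol_freq", "smoking_freq",
              "education_freq"))
    if (any(p[[v]] < 0) || sum(p[[v]]) <= 0 || is.null(names(p[[v]])))
      stop("'", v, "' must be named non-negative frequencies")
  invisible(p)
}

#' @export
print.cohort_params <- function(x, ...) {
  cat(sprintf(
    "Synthetic cohort parameters: sex %s, n = %d, seed = %d\n",
    x$sex, x$n, x$seed))
  cat(sprintf("  height %g (%g) cm; weight target %g (%g) kg; p_true = %g\n",
              x$height_mean_cm, x$height_sd_cm, x$weight_mean_kg,
              x$weight_sd_kg, x$p_true))
  cat(sprintf("  calibrated weight_scale = %.4f kg/m^p, weight_log_sd = %.4f\n",
              x$weight_scale, x$weight_log_sd))
  invisible(x)
}

# mean of a normal truncated to (lo, hi); used to center age terms so that
# marginal weight and body-fat targets are not shifted by age truncation
trunc_norm_mean <- function(mean, sd, lo, hi) {
  a <- (lo - mean) / sd
  b <- (hi - mean) / sd
  mean + sd * (stats::dnorm(a) - stats::dnorm(b)) /
    (stats::pnorm(b) - stats::pnorm(a))
}

# truncated-normal sampling by rejection; redraws only out-of-range values
rtrunc_norm <- function(n, mean, sd, lo, hi) {
  if (sd == 0) {
    if (mean <= lo || mean >= hi) stop("degenerate truncated normal")
    return(rep(mean, n))
  }
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x <= lo | x >= hi)
  it <- 0L
  while (length(bad)) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] <= lo | x[bad] >= hi]
    it <- it + 1L
    if (it > 10000L) stop("truncated-normal rejection did not terminate")
  }
  x
}

#' Generate a synthetic single-sex anthropometric cohort
#'
#' Draws `params$n` subjects with UK-population-like anthropometric
#' structure: truncated-normal height (1.2-2.2 m) and age; log-linear
#' weight-height allometry with ground-truth exponent `p_true` and residual
#' independent of height; body fat percentage linear in age and in the
#' standardized weight residual (truncated to 3-75%); waist and hip
#' circumference linear in fat mass (floored at 40 cm); relative sitting
#' height truncated to (0.40, 0.65); and categorical covariates drawn from
#' the configured frequencies. Output is bit-identical for identical
#' parameters and seed.
#'
#' @param params A [cohort_params()] object.
#' @return A data frame of class `benn_cohort` with columns `id`, `sex`,
#'   `age` (y), `height` and `sitting_height` (m), `weight`, `fat_mass`,
#'   `fat_free_mass` (kg), `bf_pct`, `wc`, `hip` (cm), `townsend`,
#'   `education`, `smoking`, `alcohol`, `ethnicity`, `follow_time` (y, NA
#'   until [generate_mortality()]), `event`. The parameter set is attached
#'   as attribute `"provenance"`.
#' @examples
#' cohort <- generate_cohort(cohort_params("F", n = 500, seed = 7))
#' summary(cohort$weight)
#' @export
generate_cohort <- function(params) {
  stopifnot(inherits(params, "cohort_params"))
  validate_cohort_params(params)
  p <- params
  set.seed(p$seed)
  n <- p$n

  height <- rtrunc_norm(n, p$height_mean_cm, p$height_sd_cm, 120, 220) / 100
  age <- rtrunc_norm(n, p$age_mean_y, p$age_sd_y, p$age_min_y, p$age_max_y)
  # center age trends at the truncated-distribution mean so the truncation
  # does not shift the marginal weight and body-fat targets
  age_c <- trunc_norm_mean(p$age_mean_y, p$age_sd_y, p$age_min_y, p$age_max_y)

  eps <- stats::rnorm(n, 0, p$weight_log_sd)
  weight <- p$weight_scale * height^p$p_true *
    exp(p$age_weight_slope * (age - age_c) + eps)
  z_w <- if (p$weight_log_sd > 0) eps / p$weight_log_sd else rep(0, n)

  bf_mu <- p$bf_mean_pct + p$bf_age_slope * (age - age_c) +
    p$bf_weight_resid_slope * z_w
  bf_noise <- stats::rnorm(n, 0, p$bf_resid_sd)
  bf <- bf_mu + bf_noise
  bad <- which(bf <= 3 | bf >= 75)
  it <- 0L
  while (length(bad) && p$bf_resid_sd > 0 && it < 100L) {
    bf[bad] <- bf_mu[bad] + stats::rnorm(length(bad), 0, p$bf_resid_sd)
    bad <- bad[bf[bad] <= 3 | bf[bad] >= 75]
    it <- it + 1L
  }
  bf <- pmin(pmax(bf, 3 + 1e-9), 75 - 1e-9)

  fat_mass <- bf * weight / 100
  fat_free_mass <- weight - fat_mass

  wc <- pmax(p$wc_intercept_cm + p$wc_fm_slope * fat_mass +
               stats::rnorm(n, 0, p$wc_sd_cm), 40)
  hip <- pmax(p$hip_intercept_cm + p$hip_fm_slope * fat_mass +
                stats::rnorm(n, 0, p$hip_sd_cm), 40)

  rsh <- rtrunc_norm(n, p$rsh_mean, p$rsh_sd, 0.40, 0.65)
  sitting_height <- rsh * height

  townsend <- stats::rnorm(n, p$townsend_mean, p$townsend_sd)
  draw_cat <- function(freq)
    factor(sample(names(freq), n, replace = TRUE, prob = freq / sum(freq)),
           levels = names(freq))
  education <- draw_cat(p$education_freq)
  smoking <- draw_cat(p$smoking_freq)
  alcohol <- draw_cat(p$alcohol_freq)
  ethnicity <- draw_cat(p$ethnicity_freq)

  cohort <- data.frame(
    id = sprintf("%s%07d", p$sex, seq_len(n)),
    sex = factor(rep(p$sex, n), levels = c("F", "M")),
    age = age, height = height, sitting_height = sitting_height,
    weight = weight, fat_mass = fat_mass, fat_free_mass = fat_free_mass,
    bf_pct = bf, wc = wc, hip = hip, townsend = townsend,
    education = education, smoking = smoking, alcohol = alcohol,
    ethnicity = ethnicity,
    follow_time = NA_real_, event = NA_integer_,
    stringsAsFactors = FALSE)
  class(cohort) <- c("benn_cohort", "data.frame")
  attr(cohort, "provenance") <- params
  cohort
}

#' Fill in survival outcomes from a proportional-hazards mortality process
#'
#' Event times are exponential with subject-specific hazard
#' `baseline_hazard * exp(log_hr_age * (age - age_mean) + log_hr_index * z)`
#' where `z` is the standardized conventional index (weight/height^2);
#' follow-up is administratively censored at `admin_censor_y` years.
#'
#' @param cohort A cohort with anthropometry fields populated.
#' @param params The [cohort_params()] holding the hazard parameters (a
#'   derived seed keeps mortality draws independent of the anthropometry
#'   draws).
#' @return The cohort with `follow_time` and `event` filled.
#' @export
generate_mortality <- function(cohort, params) {
  stopifnot(inherits(params, "cohort_params"))
  if (!all(c("age", "height", "weight") %in% names(cohort)))
    stop("anthropometry fields must be populated before mortality")
  if (!is.finite(params$baseline_hazard) || params$baseline_hazard <= 0)
    stop("'baseline_hazard' must be positive")
  set.seed((params$seed + 500009L) %% .Machine$integer.max)
  idx <- compute_index(cohort$weight, cohort$height, 2)
  z <- (idx - mean(idx)) / stats::sd(idx)
  rate <- params$baseline_hazard *
    exp(params$log_hr_age * (cohort$age - params$age_mean_y) +
          params$log_hr_index * z)
  t_event <- stats::rexp(nrow(cohort)) / rate
  cohort$event <- as.integer(t_event <= params$admin_censor_y)
  cohort$follow_time <- pmin(t_event, params$admin_censor_y)
  cohort
}

#' Sex-stratified train/test split
#'
#' Partitions a cohort into training and testing sets, stratified by sex:
#' within each sex the test share is within one subject of `test_fraction`.
#' Deterministic given `seed`.
#'
#' @param cohort A cohort data frame with a `sex` column.
#' @param test_fraction Proportion assigned to the test set, in (0, 1).
#' @param seed Integer seed for the partition.
#' @return A list with elements `train` and `test` (disjoint, union = input).
#' @export
split_train_test <- function(cohort, test_fraction = 0.2, seed = 1L) {
  if (nrow(cohort) == 0L) stop("cannot split an empty cohort")
  if (!is.numeric(test_fraction) || test_fraction <= 0 || test_fraction >= 1)
    stop("'test_fraction' must lie strictly between 0 and 1")
  set.seed(as.integer(seed))
  test_idx <- integer(0)
  for (s in unique(as.character(cohort$sex))) {
    rows <- which(as.character(cohort$sex) == s)
    k <- round(test_fraction * length(rows))
    if (k > 0L) test_idx <- c(test_idx, sample(rows, k))
  }
  test_idx <- sort(test_idx)
  list(train = cohort[setdiff(seq_len(nrow(cohort)), test_idx), , drop = FALSE],
       test = cohort[test_idx, , drop = FALSE])
}
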