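#' Configure a synthetic ICU cohort
#'
#' A `cohort_config` bundles everything the synthetic EHR generator needs to
#' emulate one source cohort: its size and demographics, length-of-stay and
#' discharge-delay distributions (log-normal, parameterised by median and
#' IQR), outcome rates, sampling cadences for vitals and laboratory results,
#' a per-sample missingness rate, and the planted outcome model — per-feature
#' log-odds coefficients for the probability of a negative outcome
#' (in-hospital death and/or ICU readmission) given the standardised
#' callout-time features.
#'
#' Two preset constructors, [mimic_like_config()] and [gicu_like_config()],
#' carry the published cohort characteristics of a large US open-access ICU
#' database ("mimic-like") and a UK general ICU ("gicu-like"): cohort size,
#' percent female, median (IQR) age, BMI, length of stay and discharge delay,
#' and in-hospital mortality / ICU readmission / composite negative-outcome
#' rates.
#'
#' @param name Cohort label, tagged onto every generated stay.
#' @param n_patients Number of stays to generate (positive integer).
#' @param frac_female Proportion of female patients, in `[0, 1]`.
#' @param age_median_iqr,bmi_median_iqr,los_median_iqr,discharge_delay_median_iqr
#'   Numeric length-3 vectors `c(median, q1, q3)`; ages in years, BMI in
#'   kg/m2, stay lengths and delays in days.
#' @param mortality_rate,readmission_rate,negative_rate Marginal probability
#'   of in-hospital death, of ICU readmission, and of their union (the
#'   composite negative outcome). Rates must satisfy
#'   `max(mortality, readmission) <= negative <= mortality + readmission`.
#' @param vitals_cadence Mean interval between vital-sign samples, minutes.
#' @param labs_cadence Mean interval between laboratory samples, hours.
#' @param missingness_rate Probability that any scheduled sample is dropped.
#' @param outcome_coefficients Named numeric vector of planted log-odds
#'   effects on the negative-outcome probability, one entry per base feature
#'   (missing features default to 0). Signs are on the standardised feature
#'   scale: a negative coefficient on `gcs_min` means higher coma scores
#'   protect against a negative outcome.
#' @param seed Integer seed fixing the generated cohort.
#'
#' @return An object of class `cohort_config` (a named list).
#' @seealso [generate_cohort()]
#' @export
#' @examples
#' cfg <- mimic_like_config(n_patients = 50, seed = 1)
#' cfg$negative_rate
cohort_config <- function(name,
                          n_patients,
                          frac_female,
                          age_median_iqr,
                          bmi_median_iqr,
                          los_median_iqr,
                          discharge_delay_median_iqr,
                          mortality_rate,
                          readmission_rate,
                          negative_rate = min(1, mortality_rate + readmission_rate),
                          vitals_cadence = 60,
                          labs_cadence = 12,
                          missingness_rate = 0.05,
                          outcome_coefficients = default_outcome_coefficients(),
                          seed = 1L) {
  if (!is.numeric(n_patients) || length(n_patients) != 1 ||
      is.na(n_patients) || n_patients < 1) {
    stop("invalid config: 'n_patients' must be a positive integer")
  }
  n_patients <- as.integer(n_patients)
  rates <- c(frac_female = frac_female, mortality_rate = mortality_rate,
             readmission_rate = readmission_rate, negative_rate = negative_rate,
             missingness_rate = missingness_rate)
  if (any(!is.finite(rates)) || any(rates < 0) || any(rates > 1)) {
    stop("invalid config: all rates must lie in [0, 1]")
  }
  if (negative_rate > mortality_rate + readmission_rate + 1e-12 ||
      negative_rate < max(mortality_rate, readmission_rate) - 1e-12) {
    stop("invalid config: 'negative_rate' inconsistent with its marginals")
  }
  if (vitals_cadence <= 0 || labs_cadence <= 0) {
    stop("invalid config: cadences must be positive")
  }
  for (q in list(age_median_iqr, bmi_median_iqr, los_median_iqr,
                 discharge_delay_median_iqr)) {
    stopifnot(length(q) == 3, all(is.finite(q)), q[2] <= q[1], q[1] <= q[3])
  }
  coefs <- setNames(numeric(length(.base_features)), .base_features)
  if (length(outcome_coefficients)) {
    unknown <- setdiff(names(outcome_coefficients), .base_features)
    if (length(unknown)) {
      stop("invalid config: unknown outcome coefficient(s): ",
           paste(unknown, collapse = ", "))
    }
    coefs[names(outcome_coefficients)] <- outcome_coefficients
  }
  structure(list(
    name = as.character(name),
    n_patients = n_patients,
    frac_female = frac_female,
    age_median_iqr = as.numeric(age_median_iqr),
    bmi_median_iqr = as.numeric(bmi_median_iqr),
    los_median_iqr = as.numeric(los_median_iqr),
    discharge_delay_median_iqr = as.numeric(discharge_delay_median_iqr),
    mortality_rate = mortality_rate,
    readmission_rate = readmission_rate,
    negative_rate = negative_rate,
    vitals_cadence = vitals_cadence,
    labs_cadence = labs_cadence,
    missingness_rate = missingness_rate,
    outcome_coefficients = coefs,
    seed = as.integer(seed)
  ), class = "cohort_config")
}

#' Default planted outcome coefficients
#'
#' Log-odds effects of the standardised callout-time features on the
#' probability of a negative outcome. The coma score and inspired-oxygen
#' fraction carry the largest magnitudes, with airway patency third; signs
#' follow the direction in which derangement moves each feature (e.g. low
#' `gcs_min` and high `fio2` both mark a patient still needing critical
#' care). Features not listed contribute nothing beyond their correlation
#' with the listed ones.
#'
#' @return Named numeric vector over a subset of the base features.
#' @export
default_outcome_coefficients <- function() {
  c(gcs_min = -1.50, fio2 = 1.10, airway = -0.90, bun = 0.45,
    hr_max = 0.35, haemoglobin = -0.30, resp_max = 0.30, hr_min = 0.20)
}

#' @rdname cohort_config
#' @export
mimic_like_config <- function(n_patients = 7592, seed = 1L, ...) {
  cohort_config(
    name = "mimic", n_patients = n_patients, seed = seed,
    frac_female = 0.476,
    age_median_iqr = c(64.0, 50.9, 77.0),
    bmi_median_iqr = c(28.1, 24.9, 31.6),
    los_median_iqr = c(1.93, 1.11, 3.34),
    discharge_delay_median_iqr = c(0.27, 0.18, 0.39),
    mortality_rate = 0.0614,
    readmission_rate = 0.0776,
    negative_rate = 0.1257,
    ...
  )
}

#' @rdname cohort_config
#' @export
gicu_like_config <- function(n_patients = 1870, seed = 2L, ...) {
  cohort_config(
    name = "gicu", n_patients = n_patients, seed = seed,
    frac_female = 0.405,
    age_median_iqr = c(63.0, 49.0, 72.8),
    bmi_median_iqr = c(26.5, 22.8, 30.6),
    los_median_iqr = c(2.96, 1.69, 5.14),
    discharge_delay_median_iqr = c(0.34, 0.20, 1.04),
    mortality_rate = 0.0358,
    readmission_rate = 0.0278,
    negative_rate = 0.0583,
    ...
  )
}

# Draw n values from a log-normal fitted to a printed median and IQR.
# meanlog = log(median); sdlog from the normal-quantile spread of the
# log-quartiles. Suits the positively skewed stay lengths.
.rlnorm_median_iqr <- function(n, median_iqr, lower = -Inf, upper = Inf) {
  m <- median_iqr[1]; q1 <- median_iqr[2]; q3 <- median_iqr[3]
  sdlog <- if (q3 > q1 && q1 > 0) (log(q3) - log(q1)) / (2 * qnorm(0.75)) else 0
  x <- rlnorm(n, meanlog = log(m), sdlog = sdlog)
  pmin(pmax(x, lower), upper)
}
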