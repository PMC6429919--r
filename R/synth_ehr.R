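#' Generate a synthetic ICU cohort
#'
#' Simulates `n_patients` ICU stays with the event structure, sampling
#' cadence and missingness of a routinely collected critical-care dataset,
#' and a *planted* physiology-to-outcome model that downstream classifiers
#' can be tested against.
#'
#' Each stay gets an admission at minute 0, a callout (declared
#' ready-for-discharge) time, and an ICU discharge time, with length of stay
#' and discharge delay drawn from log-normals fitted to the configured
#' median/IQR. Every clinical variable follows a per-patient derangement
#' baseline plus AR(1) observation noise plus a linear recovery ramp that
#' pulls the value toward its normal band as time approaches callout;
#' patients with a large latent *stall* fraction remain short of normal at
#' callout. Vitals are sampled on a regular minutes-scale grid, laboratory
#' variables every `labs_cadence` hours, and each scheduled sample is
#' dropped independently with probability `missingness_rate`.
#'
#' Outcome flags are then drawn from a logistic model on the stay's own
#' physiology: the 18 base features are extracted at callout, standardised
#' across the cohort, combined with `config$outcome_coefficients`, and the
#' intercept is calibrated so the expected negative-outcome fraction equals
#' `config$negative_rate`. Negative outcomes are split into in-hospital
#' death and/or ICU readmission so that both configured marginal rates are
#' honoured.
#'
#' The same seed always reproduces the identical cohort; the caller's RNG
#' state is left untouched.
#'
#' @param config A [cohort_config()].
#' @return An object of class `icu_cohort`: a list of `patient_stay` objects
#'   with the generating config attached as attribute `config`.
#' @export
#' @examples
#' coh <- generate_cohort(mimic_like_config(n_patients = 20, seed = 3))
#' length(coh)
#' coh[[1]]$callout_time
generate_cohort <- function(config) {
  if (!inherits(config, "cohort_config")) {
    stop("invalid config: expected a 'cohort_config' object")
  }
  old_seed <- .save_rng()
  on.exit(.restore_rng(old_seed), add = TRUE)
  set.seed(config$seed)

  n <- config$n_patients
  cat_tab <- .variable_catalog()

  sex <- rbinom(n, 1, config$frac_female)                       # 1 = female
  age <- round(.rlnorm_median_iqr(n, config$age_median_iqr, 18, 100), 1)
  bmi <- round(.rlnorm_median_iqr(n, config$bmi_median_iqr, 13, 60), 1)
  los_days <- .rlnorm_median_iqr(n, config$los_median_iqr, 0.25, 60)
  delay_days <- .rlnorm_median_iqr(n, config$discharge_delay_median_iqr,
                                   0.05, 20)
  delay_days <- pmin(delay_days, 0.6 * los_days)
  discharge_min <- pmax(round(los_days * 1440), 120)
  callout_min <- pmax(round((los_days - delay_days) * 1440), 60)
  callout_min <- pmin(callout_min, discharge_min)

  # latent illness course: overall severity scales the admission
  # derangement; the stall fraction is how much of it persists at callout
  severity <- rlnorm(n, meanlog = 0, sdlog = 0.25)
  stall <- rbeta(n, 1.2, 8)

  stays <- vector("list", n)
  for (i in seq_len(n)) {
    stays[[i]] <- .generate_stay(
      id = sprintf("%s-%05d", config$name, i),
      config = config, cat_tab = cat_tab,
      callout = callout_min[i], discharge = discharge_min[i],
      age = age[i], sex = sex[i], bmi = bmi[i],
      severity = severity[i], stall = stall[i]
    )
  }

  outcomes <- .draw_outcomes(stays, config)
  for (i in seq_len(n)) {
    stays[[i]]$died_in_hospital <- outcomes$died[i]
    stays[[i]]$readmitted <- outcomes$readmitted[i]
  }
  structure(stays, class = "icu_cohort", config = config)
}

#' @export
print.icu_cohort <- function(x, ...) {
  cfg <- attr(x, "config")
  neg <- vapply(x, function(s) s$died_in_hospital || s$readmitted, logical(1))
  cat(sprintf("<icu_cohort> source '%s': %d stays, %.2f%% negative outcomes\n",
              cfg$name, length(x), 100 * mean(neg)))
  invisible(x)
}

# minimal-overhead data.frame constructor (hot path: 15 series per stay)
.fast_df <- function(t_minutes, value) {
  structure(list(t_minutes = as.integer(t_minutes), value = as.numeric(value)),
            class = "data.frame",
            row.names = .set_row_names(length(t_minutes)))
}
.set_row_names <- function(n) if (n) c(NA_integer_, -n) else integer(0)

.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.restore_rng <- function(seed) {
  if (is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", seed, envir = globalenv())
  }
}

.generate_stay <- function(id, config, cat_tab, callout, discharge,
                           age, sex, bmi, severity, stall) {
  series <- vector("list", nrow(cat_tab))
  names(series) <- cat_tab$variable
  phi <- 0.7  # AR(1) autocorrelation of observation noise

  for (j in seq_len(nrow(cat_tab))) {
    v <- cat_tab[j, ]
    step <- if (v$kind == "vital") config$vitals_cadence else
      config$labs_cadence * 60
    tt <- seq(0L, discharge, by = as.integer(round(step)))
    m <- length(tt)

    # recovery ramp: 1 at admission, per-variable stall level at callout
    stall_v <- min(1, stall * runif(1, 0.6, 1.4))
    ramp <- 1 - (1 - stall_v) * pmin(tt / callout, 1)
    dir <- if (v$direction == 0) sample(c(-1, 1), 1) else v$direction
    amplitude <- dir * v$derange_scale * severity * runif(1, 0.7, 1.3)

    eps <- rnorm(m, 0, v$noise_sd * sqrt(1 - phi^2))
    noise <- as.numeric(stats::filter(eps, phi, method = "recursive",
                                      init = rnorm(1, 0, v$noise_sd)))
    if (v$variable == "airway") {
      val <- as.numeric(severity * ramp + rnorm(m, 0, 0.3) < 0.55)
    } else {
      val <- v$normal_mid + amplitude * ramp + noise
      val <- .clamp_variable(v$variable, val)
    }

    keep <- runif(m) >= config$missingness_rate
    series[[j]] <- .fast_df(tt[keep], val[keep])
  }

  structure(list(
    stay_id = id,
    source = config$name,
    admission_time = 0L,
    callout_time = as.integer(callout),
    icu_discharge_time = as.integer(discharge),
    age = age, sex = sex, bmi = bmi,
    died_in_hospital = FALSE, readmitted = FALSE,
    series = series
  ), class = "patient_stay")
}

# variable-specific physical clamps / rounding
.clamp_variable <- function(variable, val) {
  switch(variable,
    # FiO2 is clinician-set in coarse steps, not a continuous measurement
    fio2 = pmin(pmax(round(val / 0.05) * 0.05, 0.21), 1),
    spo2 = round(pmin(pmax(val, 0), 100), 1),
    gcs = round(pmin(pmax(round(val), 3), 15)),
    pain = round(pmin(pmax(round(val), 0), 10)),
    temp = round(pmax(val, 30), 1),
    hr = round(pmax(val, 20)),
    resp = round(pmax(val, 4)),
    bp = round(pmax(val, 40)),
    hco3 = round(pmax(val, 5), 1),
    haemoglobin = round(pmax(val, 30)),
    k = round(pmax(val, 1.5), 2),
    na = round(pmax(val, 110)),
    creatinine = round(pmax(val, 20)),
    bun = round(pmax(val, 0.5), 1),
    val
  )
}

# Outcome flags from the planted logistic model on callout physiology.
.draw_outcomes <- function(stays, config) {
  n <- length(stays)
  if (config$negative_rate == 0) {
    return(list(died = rep(FALSE, n), readmitted = rep(FALSE, n)))
  }
  X <- t(vapply(stays, function(s) {
    unlist(extract_features(s, s$callout_time), use.names = FALSE)
  }, numeric(length(.base_features))))
  colnames(X) <- .base_features
  Z <- apply(X, 2, function(col) {
    mu <- mean(col, na.rm = TRUE)
    sdev <- sd(col, na.rm = TRUE)
    z <- if (is.finite(sdev) && sdev > 0) (col - mu) / sdev else col * 0
    z[!is.finite(z)] <- 0
    z
  })
  eta <- as.numeric(Z %*% config$outcome_coefficients)
  # calibrate the intercept so E[p] hits the configured composite rate
  target <- config$negative_rate
  f <- function(c0) mean(plogis(c0 + eta)) - target
  intercept <- uniroot(f, interval = c(-40, 40), tol = 1e-10)$root
  p_neg <- plogis(intercept + eta)
  neg <- runif(n) < p_neg

  # split the composite into death / readmission honouring both marginals:
  # overlapping sub-intervals of [0,1] cover it, so every negative stay
  # carries at least one flag
  q_died <- config$mortality_rate / config$negative_rate
  q_read <- config$readmission_rate / config$negative_rate
  u <- runif(n)
  died <- neg & (u < q_died)
  readmitted <- neg & (u > 1 - q_read)
  list(died = died, readmitted = readmitted)
}

#' Validate a patient stay against its structural invariants
#'
#' Checks event-time ordering, that every observation falls inside the stay,
#' and the physical ranges of the bounded variables (GCS integer in 3–15,
#' FiO2 in 0.21–1, SpO2 in 0–100, pain integer in 0–10, airway binary).
#'
#' @param stay A `patient_stay`.
#' @return Invisibly `TRUE`; stops with a descriptive error on violation.
#' @export
validate_stay <- function(stay) {
  stopifnot(inherits(stay, "patient_stay"))
  with(stay, {
    if (!(admission_time < callout_time && callout_time <= icu_discharge_time))
      stop("stay ", stay_id, ": event times must satisfy admission < callout <= discharge")
  })
  for (v in names(stay$series)) {
    s <- stay$series[[v]]
    if (!nrow(s)) next
    if (any(s$t_minutes < stay$admission_time |
            s$t_minutes > stay$icu_discharge_time)) {
      stop("stay ", stay$stay_id, ": '", v, "' has timestamps outside the stay")
    }
    val <- s$value
    ok <- switch(v,
      gcs = all(val == round(val) & val >= 3 & val <= 15),
      fio2 = all(val >= 0.21 & val <= 1),
      spo2 = all(val >= 0 & val <= 100),
      pain = all(val == round(val) & val >= 0 & val <= 10),
      airway = all(val %in% c(0, 1)),
      TRUE
    )
    if (!ok) stop("stay ", stay$stay_id, ": '", v, "' violates its physical range")
  }
  invisible(TRUE)
}

#' Write / read a cohort as plain CSV files
#'
#' `write_cohort()` stores a cohort as two CSVs under `path`:
#' `stays.csv` (one row per stay: identifiers, event times in minutes since
#' admission, demographics, outcome flags) and `observations.csv`
#' (long format: `stay_id, variable, t_minutes, value`). `read_cohort()`
#' reverses it losslessly; variables with no observations for a stay come
#' back as present-but-empty series. Rows violating the stay invariants
#' (e.g. an observation time outside the stay) raise a parse error naming
#' the offending line.
#'
#' @param cohort An `icu_cohort` (or plain list of `patient_stay`).
#' @param path Directory to write into (created if needed).
#' @return `write_cohort()` the path, invisibly; `read_cohort()` an
#'   `icu_cohort`.
#' @export
write_cohort <- function(cohort, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  meta <- data.table::rbindlist(lapply(cohort, function(s) {
    data.table::data.table(
      stay_id = s$stay_id, source = s$source,
      admission_time = s$admission_time, callout_time = s$callout_time,
      icu_discharge_time = s$icu_discharge_time,
      age = s$age, sex = s$sex, bmi = s$bmi,
      died_in_hospital = s$died_in_hospital, readmitted = s$readmitted
    )
  }))
  obs <- data.table::rbindlist(lapply(cohort, function(s) {
    nper <- vapply(s$series, nrow, integer(1))
    data.table::data.table(
      stay_id = s$stay_id,
      variable = rep(names(s$series), nper),
      t_minutes = unlist(lapply(s$series, `[[`, "t_minutes"), use.names = FALSE),
      value = unlist(lapply(s$series, `[[`, "value"), use.names = FALSE)
    )
  }))
  data.table::fwrite(meta, file.path(path, "stays.csv"))
  data.table::fwrite(obs, file.path(path, "observations.csv"))
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  meta <- data.table::fread(file.path(path, "stays.csv"))
  obs <- data.table::fread(file.path(path, "observations.csv"))
  required <- c("stay_id", "variable", "t_minutes", "value")
  if (!all(required %in% names(obs))) {
    stop("parse error: observations.csv must have columns ",
         paste(required, collapse = ", "))
  }
  bad <- which(!is.finite(obs$t_minutes) | !is.finite(obs$value))
  if (length(bad)) {
    stop("parse error at observations.csv line ", bad[1] + 1L,
         ": non-numeric t_minutes/value")
  }
  variables <- .variable_catalog()$variable
  span <- meta[match(obs$stay_id, meta$stay_id), ]
  outside <- which(obs$t_minutes < span$admission_time |
                   obs$t_minutes > span$icu_discharge_time)
  if (length(outside)) {
    stop("parse error at observations.csv line ", outside[1] + 1L,
         ": timestamp outside the stay interval")
  }
  obs_split <- split(obs, obs$stay_id)
  stays <- lapply(seq_len(nrow(meta)), function(i) {
    m <- meta[i, ]
    so <- obs_split[[m$stay_id]]
    series <- setNames(vector("list", length(variables)), variables)
    for (v in variables) {
      if (!is.null(so)) {
        sv <- so[so$variable == v, ]
        series[[v]] <- .fast_df(sv$t_minutes, sv$value)
      } else {
        series[[v]] <- .fast_df(integer(0), numeric(0))
      }
    }
    structure(list(
      stay_id = m$stay_id, source = m$source,
      admission_time = as.integer(m$admission_time),
      callout_time = as.integer(m$callout_time),
      icu_discharge_time = as.integer(m$icu_discharge_time),
      age = m$age, sex = m$sex, bmi = m$bmi,
      died_in_hospital = as.logical(m$died_in_hospital),
      readmitted = as.logical(m$readmitted),
      series = series
    ), class = "patient_stay")
  })
  structure(stays, class = "icu_cohort")
}
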