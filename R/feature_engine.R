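#' Extract windowed features for one stay at a reference time
#'
#' Computes the 18 base features (optionally plus the 4 extended features)
#' from the observations in the half-open window `(t_ref - 4 h, t_ref]`.
#' For any variable with no observation in that window an extended
#' `(t_ref - 36 h, t_ref]` fallback window is used — mainly relevant for
#' infrequently measured laboratory results. A variable absent from both
#' windows yields `NA` (a missing marker for downstream imputation).
#'
#' Aggregation over the window: paired features take the window min/max
#' (`resp_min`/`resp_max`, `hr_min`/`hr_max`, `temp_min`/`temp_max`);
#' single-feature vitals take the clinically conservative extreme —
#' `fio2` and `pain` the maximum, `spo2_min`, `bp_min`, `gcs_min` and
#' `airway` the minimum (airway is binary with 1 = patent, so the minimum is
#' the worst state); laboratory values (`hco3`, `haemoglobin`, `k`, `na`,
#' `creatinine`, `bun`) take the most recent observation.
#'
#' @param stay A `patient_stay`.
#' @param t_ref Reference time, minutes since admission; must not precede
#'   admission.
#' @param window_hours,fallback_hours Window lengths in hours.
#' @param extended Include `age`, `sex`, `bmi`, `hours_since_admission`?
#' @return Named numeric vector of 18 (or 22) features, `NA` where missing.
#' @export
#' @examples
#' coh <- generate_cohort(gicu_like_config(n_patients = 3, seed = 9))
#' extract_features(coh[[1]], coh[[1]]$callout_time)
extract_features <- function(stay, t_ref, window_hours = 4,
                             fallback_hours = 36, extended = FALSE) {
  if (t_ref < stay$admission_time) {
    stop("t_ref precedes admission for stay ", stay$stay_id)
  }
  spec <- .feature_spec()
  out <- setNames(rep(NA_real_, nrow(spec)), spec$feature)
  win_lo <- t_ref - window_hours * 60
  fb_lo <- t_ref - fallback_hours * 60
  for (v in unique(spec$variable)) {
    s <- stay$series[[v]]
    if (is.null(s) || !nrow(s)) next
    sel <- s$t_minutes > win_lo & s$t_minutes <= t_ref
    if (!any(sel)) sel <- s$t_minutes > fb_lo & s$t_minutes <= t_ref
    if (!any(sel)) next
    tt <- s$t_minutes[sel]; vals <- s$value[sel]
    rows <- which(spec$variable == v)
    for (r in rows) {
      out[spec$feature[r]] <- switch(spec$agg[r],
        min = min(vals),
        max = max(vals),
        last = vals[which.max(tt)]
      )
    }
  }
  if (extended) {
    out <- c(out,
             age = stay$age, sex = as.numeric(stay$sex), bmi = stay$bmi,
             hours_since_admission = (t_ref - stay$admission_time) / 60)
  }
  out
}

#' Build the instance-by-feature matrix for a labelled dataset
#'
#' Runs [extract_features()] for every labelled instance at its reference
#' time, returning a numeric matrix with one row per instance, in the order
#' of `instances`.
#'
#' @param instances data.frame from [build_dataset()] (needs `stay_id`,
#'   `t_ref`), with its `stays` attribute, or supply `stays` explicitly.
#' @param stays Named list of `patient_stay` objects keyed by `stay_id`.
#' @param extended Include the 4 extended features?
#' @inheritParams extract_features
#' @return Numeric matrix, `nrow(instances)` x 18 (or 22).
#' @export
build_feature_matrix <- function(instances, stays = attr(instances, "stays"),
                                 window_hours = 4, fallback_hours = 36,
                                 extended = FALSE) {
  if (is.null(stays)) stop("no 'stays' attached to the instances")
  p <- length(.base_features) + if (extended) 4L else 0L
  X <- matrix(NA_real_, nrow(instances), p)
  for (i in seq_len(nrow(instances))) {
    st <- stays[[instances$stay_id[i]]]
    if (is.null(st)) stop("unknown stay_id: ", instances$stay_id[i])
    X[i, ] <- extract_features(st, instances$t_ref[i], window_hours,
                               fallback_hours, extended = extended)
  }
  colnames(X) <- c(.base_features, if (extended) .extended_features)
  X
}

#' k-nearest-neighbour imputation of a feature matrix
#'
#' Fills each missing cell with the mean of that feature over the `k`
#' nearest instances. Distances are Euclidean on the mutually observed
#' features after internal standardisation, rescaled by the fraction of
#' usable coordinates (the `nan`-aware Euclidean convention), so rows with
#' different missingness patterns remain comparable. Only neighbours with
#' the target feature observed are candidates; ties are broken by row
#' order. Observed cells are never altered.
#'
#' @param X Numeric matrix with `NA` missing markers.
#' @param k Number of neighbours (`>= 1`).
#' @return Completed matrix of the same shape.
#' @export
knn_impute <- function(X, k = 5) {
  stopifnot(is.matrix(X), k >= 1)
  p <- ncol(X)
  all_missing <- colSums(!is.na(X)) == 0
  if (any(all_missing)) {
    stop("cannot impute fully-missing feature(s): ",
         paste(colnames(X)[all_missing], collapse = ", "))
  }
  if (!anyNA(X)) return(X)
  mu <- colMeans(X, na.rm = TRUE)
  sdev <- apply(X, 2, sd, na.rm = TRUE)
  sdev[!is.finite(sdev) | sdev == 0] <- 1
  Z <- sweep(sweep(X, 2, mu, "-"), 2, sdev, "/")
  obs <- !is.na(Z)
  Z0 <- Z; Z0[!obs] <- 0
  # pairwise nan-Euclidean squared distances:
  # sum over mutually observed coords, scaled by p / (#mutual coords)
  G <- Z0 %*% t(Z0)
  S <- (Z0^2) %*% t(obs)          # sum z_i^2 over coords observed in both
  M <- obs %*% t(obs)             # mutual observation counts
  D2 <- S + t(S) - 2 * G
  D2 <- D2 * p / pmax(M, 1)
  D2[M == 0] <- Inf
  out <- X
  need <- which(is.na(X), arr.ind = TRUE)
  for (f in unique(need[, 2])) {
    rows_missing <- need[need[, 2] == f, 1]
    donors <- which(obs[, f])
    for (i in rows_missing) {
      d <- D2[i, donors]
      keep <- is.finite(d) & donors != i
      cand <- donors[keep][order(d[keep], donors[keep])]
      nn <- head(cand, k)
      if (!length(nn)) {
        out[i, f] <- mu[f]        # no usable neighbour: column mean
      } else {
        out[i, f] <- mean(X[nn, f])
      }
    }
  }
  out
}

#' Standardise feature matrices with training-set parameters
#'
#' Centres and scales every matrix by the column means and sample SDs of the
#' *training* matrix only, so no information leaks from evaluation data into
#' the transform. Zero-variance training columns map to 0 everywhere.
#'
#' @param train Numeric training matrix (non-empty).
#' @param ... Further matrices to transform with the training parameters.
#' @return List with `train`, one transformed entry per extra matrix (named
#'   as passed), and `center`/`scale` vectors.
#' @export
standardise <- function(train, ...) {
  if (is.null(dim(train)) || nrow(train) == 0) {
    stop("empty training matrix")
  }
  center <- colMeans(train)
  scale <- apply(train, 2, sd)
  zero <- !is.finite(scale) | scale == 0
  scale[zero] <- 1
  tf <- function(m) {
    z <- sweep(sweep(m, 2, center, "-"), 2, scale, "/")
    if (any(zero)) z[, zero] <- 0
    z
  }
  others <- list(...)
  out <- c(list(train = tf(train)), lapply(others, tf))
  out$center <- center
  out$scale <- scale
  out
}
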