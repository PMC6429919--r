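#' Codified nurse-led discharge thresholds
#'
#' The fifteen nurse-led discharge (NLD) tests as a table of inclusive
#' bounds on the windowed features. Test IDs group into respiratory
#' (R0–R4), cardiovascular (C0–C1), pain (P), central nervous system (CNS),
#' temperature (T) and bloods (B0–B4). Defaults:
#'
#' | ID  | condition                           |
#' |-----|-------------------------------------|
#' | R0  | airway patent                       |
#' | R1  | fio2 <= 0.6                         |
#' | R2  | spo2 >= 95 %                        |
#' | R3  | hco3 >= 19 mmol/L                   |
#' | R4  | 10 <= resp <= 30 bpm                |
#' | C0  | systolic bp >= 100 mm Hg            |
#' | C1  | 60 <= hr <= 100 bpm                 |
#' | P   | 0 <= pain <= 1 (0–10 scale)         |
#' | CNS | gcs >= 14                           |
#' | T   | 36 <= temp <= 37.5 C                |
#' | B0  | haemoglobin >= 90 g/L               |
#' | B1  | 3.5 <= k <= 6.0 mmol/L              |
#' | B2  | 130 <= na <= 150 mmol/L             |
#' | B3  | 59 <= creatinine <= 104 umol/L      |
#' | B4  | 2.5 <= bun <= 7.8 mmol/L            |
#'
#' The blood and CNS bounds were not numeric in the original criteria and
#' default to typical clinical-information-system "normal" ranges; every
#' bound is overridable.
#'
#' @param overrides Optional named list, e.g.
#'   `list(CNS = c(lower = 13))`; an `NA` or absent side is left at its
#'   default.
#' @return A `data.frame` of class `nld_thresholds` with columns `test_id`,
#'   `variable`, `lower`, `upper`, `units`.
#' @export
#' @examples
#' nld_thresholds()
#' nld_thresholds(list(R1 = c(lower = NA, upper = 0.5)))
nld_thresholds <- function(overrides = NULL) {
  th <- data.frame(
    test_id = .test_ids,
    variable = c("airway", "fio2", "spo2", "hco3", "resp", "bp", "hr",
                 "pain", "gcs", "temp", "haemoglobin", "k", "na",
                 "creatinine", "bun"),
    lower = c(1, NA, 95, 19, 10, 100, 60, 0, 14, 36, 90, 3.5, 130, 59, 2.5),
    upper = c(1, 0.6, NA, NA, 30, NA, 100, 1, NA, 37.5, NA, 6.0, 150, 104, 7.8),
    units = c("binary", "fraction", "%", "mmol/L", "bpm", "mm Hg", "bpm",
              "0-10 scale", "score", "degC", "g/L", "mmol/L", "mmol/L",
              "umol/L", "mmol/L"),
    stringsAsFactors = FALSE
  )
  if (!is.null(overrides)) {
    for (id in names(overrides)) {
      i <- match(id, th$test_id)
      if (is.na(i)) stop("invalid threshold: unknown test ID '", id, "'")
      o <- overrides[[id]]
      if (!is.null(o["lower"]) && !is.na(o["lower"])) th$lower[i] <- o[["lower"]]
      if (!is.null(o["upper"]) && !is.na(o["upper"])) th$upper[i] <- o[["upper"]]
    }
  }
  .validate_thresholds(th)
  structure(th, class = c("nld_thresholds", "data.frame"))
}

.validate_thresholds <- function(th) {
  if (nrow(th) != 15 || !setequal(th$test_id, .test_ids)) {
    stop("invalid thresholds: exactly the 15 discharge tests are required")
  }
  two_sided <- !is.na(th$lower) & !is.na(th$upper) & th$test_id != "R0"
  if (any(two_sided & th$lower >= th$upper)) {
    bad <- th$test_id[two_sided & th$lower >= th$upper]
    stop("invalid threshold: inverted bounds for ", paste(bad, collapse = ", "))
  }
  invisible(TRUE)
}

#' Read or write discharge thresholds as YAML/JSON
#'
#' Serialises the threshold table to a YAML (default) or JSON file mirroring
#' the codified criteria table: test ID, variable, bounds and units.
#'
#' @param thresholds An [nld_thresholds()] table.
#' @param path File path; format chosen by extension (`.yaml`/`.yml`/`.json`).
#' @return `write_thresholds()` the path invisibly; `read_thresholds()` an
#'   `nld_thresholds` table.
#' @export
write_thresholds <- function(thresholds, path) {
  recs <- lapply(seq_len(nrow(thresholds)), function(i) {
    as.list(thresholds[i, c("test_id", "variable", "lower", "upper", "units")])
  })
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA,
                         na = "null")
  } else {
    yaml::write_yaml(recs, path)
  }
  invisible(path)
}

#' @rdname write_thresholds
#' @export
read_thresholds <- function(path) {
  recs <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path)
  } else {
    yaml::read_yaml(path)
  }
  th <- data.frame(
    test_id = vapply(recs, function(r) r$test_id, character(1)),
    variable = vapply(recs, function(r) r$variable, character(1)),
    lower = vapply(recs, function(r) if (is.null(r$lower) || is.na(r$lower))
      NA_real_ else as.numeric(r$lower), numeric(1)),
    upper = vapply(recs, function(r) if (is.null(r$upper) || is.na(r$upper))
      NA_real_ else as.numeric(r$upper), numeric(1)),
    units = vapply(recs, function(r) r$units, character(1)),
    stringsAsFactors = FALSE
  )
  .validate_thresholds(th)
  structure(th, class = c("nld_thresholds", "data.frame"))
}

#' Evaluate the fifteen discharge tests on a feature vector
#'
#' Applies each codified test to the corresponding windowed feature(s) with
#' inclusive bounds. Two-feature tests (R4 respiratory rate, C1 heart rate,
#' T temperature) pass iff the window minimum respects the lower bound *and*
#' the window maximum respects the upper bound. A test whose input feature
#' is missing (`NA`) fails and is recorded in `tests_with_missing_inputs` —
#' a deliberately conservative policy, since upstream imputation makes
#' missing inputs rare.
#'
#' @param features Named numeric vector (or single-row data.frame) holding at
#'   least the 18 base features; `NA` marks a missing value.
#' @param thresholds An [nld_thresholds()] table.
#' @return An object of class `criteria_result`: list with `passed` (named
#'   logical, length 15), `n_passed`, and `tests_with_missing_inputs`.
#' @export
#' @examples
#' f <- boundary_feature_vector()
#' evaluate_tests(f)$n_passed  # 15: boundary values pass inclusively
evaluate_tests <- function(features, thresholds = nld_thresholds()) {
  .validate_thresholds(thresholds)
  if (is.data.frame(features)) features <- unlist(features[1, , drop = TRUE])
  fmap <- .test_features()
  passed <- setNames(logical(15), .test_ids)
  missing_in <- character(0)
  for (id in .test_ids) {
    i <- match(id, thresholds$test_id)
    lo <- thresholds$lower[i]; hi <- thresholds$upper[i]
    feats <- fmap[[id]]
    x <- suppressWarnings(as.numeric(features[feats]))
    if (any(is.na(x)) || length(x) != length(feats)) {
      missing_in <- c(missing_in, id)
      passed[id] <- FALSE
      next
    }
    if (length(x) == 2) {
      ok <- x[1] >= lo && x[2] <= hi   # (min-feature, max-feature) pair
    } else {
      ok <- (is.na(lo) || x >= lo) && (is.na(hi) || x <= hi)
    }
    passed[id] <- ok
  }
  structure(list(passed = passed,
                 n_passed = sum(passed),
                 tests_with_missing_inputs = missing_in),
            class = "criteria_result")
}

#' @export
print.criteria_result <- function(x, ...) {
  cat(sprintf("<criteria_result> %d/15 passed", x$n_passed))
  if (length(x$tests_with_missing_inputs)) {
    cat("; missing inputs:", paste(x$tests_with_missing_inputs, collapse = ", "))
  }
  cat("\n")
  invisible(x)
}

#' Count-based NLD probability score
#'
#' Number of tests passed divided by 15 — a probability-like readiness score
#' in which each criterion contributes equally. Thresholding it at k/15 for
#' k = 0..15 recovers the "at least k criteria met" rule family, which is
#' how the criteria trace out a ROC curve.
#'
#' @param result A `criteria_result` from [evaluate_tests()].
#' @return A score in `[0, 1]`.
#' @export
nld_score <- function(result) {
  stopifnot(inherits(result, "criteria_result"))
  result$n_passed / 15
}

#' Importance-weighted NLD score
#'
#' Convex combination of the per-test pass flags under normalised,
#' non-negative weights; with uniform weights this reduces to [nld_score()].
#'
#' @param result A `criteria_result`.
#' @param weights Named numeric vector of 15 non-negative weights (one per
#'   test ID) summing to 1, e.g. from [weights_from_importance()].
#' @return A score in `[0, 1]`.
#' @export
weighted_score <- function(result, weights) {
  stopifnot(inherits(result, "criteria_result"))
  if (any(weights < 0)) stop("invalid weights: negative weight")
  if (!setequal(names(weights), .test_ids)) {
    stop("invalid weights: need exactly one weight per test ID")
  }
  w <- weights[.test_ids]
  s <- sum(w)
  if (abs(s - 1) > 1e-8) w <- w / s
  sum(w * result$passed[.test_ids])
}

#' Criteria weights from feature importances
#'
#' Maps per-feature importances (e.g. permutation importances of the
#' logistic classifier) onto the fifteen tests: each test's weight is the
#' sum of its constituent features' importances, floored at zero, then
#' normalised to sum 1. If every floored importance is zero the weights fall
#' back to uniform with a warning.
#'
#' @param importances Named numeric vector covering all 18 base features.
#' @return Named numeric vector of 15 weights summing to 1.
#' @export
weights_from_importance <- function(importances) {
  missing <- setdiff(.base_features, names(importances))
  if (length(missing)) {
    stop("missing importance for feature(s): ", paste(missing, collapse = ", "))
  }
  imp <- pmax(importances[.base_features], 0)
  fmap <- .test_features()
  w <- vapply(.test_ids, function(id) sum(imp[fmap[[id]]]), numeric(1))
  if (sum(w) == 0) {
    warning("all importances non-positive; falling back to uniform weights")
    w <- rep(1, 15)
  }
  setNames(w / sum(w), .test_ids)
}

#' Boundary-value feature vector
#'
#' A feature vector sitting exactly on the printed inclusive bound of every
#' test (the lower bound for `>=`-type conditions, the upper bound for
#' `<=`-type, and both for two-sided paired tests). Because all bounds are
#' inclusive it passes all 15 tests.
#'
#' @param thresholds An [nld_thresholds()] table.
#' @return Named numeric vector of the 18 base features.
#' @export
boundary_feature_vector <- function(thresholds = nld_thresholds()) {
  fmap <- .test_features()
  out <- setNames(numeric(length(.base_features)), .base_features)
  for (id in .test_ids) {
    i <- match(id, thresholds$test_id)
    lo <- thresholds$lower[i]; hi <- thresholds$upper[i]
    feats <- fmap[[id]]
    if (length(feats) == 2) {
      out[feats[1]] <- lo
      out[feats[2]] <- hi
    } else {
      out[feats] <- if (!is.na(lo)) lo else hi
    }
  }
  out
}

#' Sustained readiness-for-discharge flag
#'
#' Implements the original all-criteria discharge rule: the patient may be
#' flagged ready iff all 15 tests hold throughout a trailing window
#' (default 4 h) ending at `at_time`. Data are discrete samples, so the
#' rule is evaluated on the observation grid: each variable must have at
#' least one observation inside the window, and every one of its in-window
#' observations must satisfy its test bounds. A test whose variable has no
#' in-window observation counts as failed (missing-as-fail).
#'
#' @param stay A `patient_stay`.
#' @param at_time Reference time, minutes since admission; must lie inside
#'   the stay.
#' @param window_hours Length of the trailing window, hours.
#' @param thresholds An [nld_thresholds()] table.
#' @return Logical flag, with attribute `result` holding the per-test detail.
#' @export
sustained_rfd <- function(stay, at_time, window_hours = 4,
                          thresholds = nld_thresholds()) {
  .validate_thresholds(thresholds)
  if (at_time < stay$admission_time || at_time > stay$icu_discharge_time) {
    stop("at_time outside the stay interval")
  }
  lo_t <- at_time - window_hours * 60
  fmap <- .test_features()
  passed <- setNames(logical(15), .test_ids)
  missing_in <- character(0)
  for (id in .test_ids) {
    i <- match(id, thresholds$test_id)
    v <- thresholds$variable[i]
    s <- stay$series[[v]]
    vals <- if (is.null(s)) numeric(0) else
      s$value[s$t_minutes > lo_t & s$t_minutes <= at_time]
    if (!length(vals)) {
      missing_in <- c(missing_in, id)
      passed[id] <- FALSE
      next
    }
    lo <- thresholds$lower[i]; hi <- thresholds$upper[i]
    passed[id] <- (is.na(lo) || all(vals >= lo)) &&
      (is.na(hi) || all(vals <= hi))
  }
  res <- structure(list(passed = passed, n_passed = sum(passed),
                        tests_with_missing_inputs = missing_in),
                   class = "criteria_result")
  structure(all(passed), result = res)
}
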