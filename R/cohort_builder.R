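#' Label a stay at its callout time
#'
#' A patient is ready-for-discharge (RFD) at callout iff they subsequently
#' left hospital alive and were never readmitted to the ICU during the same
#' hospital admission; in-hospital death and/or readmission makes the
#' callout instance NRFD. A stay with both flags still yields a single NRFD
#' instance.
#'
#' @param stay A `patient_stay`.
#' @return One-row data.frame with columns `stay_id`, `source`, `t_ref`
#'   (minutes since admission), `label` (`"RFD"`/`"NRFD"`) and `provenance`
#'   (`"callout"`), or `NULL` with a warning if the stay has no callout.
#' @export
label_at_callout <- function(stay) {
  if (is.null(stay$callout_time) || is.na(stay$callout_time)) {
    warning("stay ", stay$stay_id, " has no callout time; skipped")
    return(NULL)
  }
  negative <- isTRUE(stay$died_in_hospital) || isTRUE(stay$readmitted)
  data.frame(
    stay_id = stay$stay_id, source = stay$source,
    t_ref = as.integer(stay$callout_time),
    label = if (negative) "NRFD" else "RFD",
    provenance = "callout",
    stringsAsFactors = FALSE
  )
}

# Valid augmentation interval for one stay, in minutes since admission:
# between 3 and 8 days before callout, and at least 24 h after admission.
.augment_interval <- function(stay) {
  lo <- max(stay$callout_time - 8 * 1440, stay$admission_time + 24 * 60)
  hi <- stay$callout_time - 3 * 1440
  c(lo = lo, hi = hi)
}

#' Sample augmented negative-class instances
#'
#' Negative-outcome callouts are rare, so extra NRFD instances are sampled
#' from points 3–8 days *before* callout, under the assumption that the
#' patient still required critical care then, regardless of their eventual
#' outcome. Reference times are drawn uniformly (integer minutes) from the
#' window `[callout - 8 d, callout - 3 d]` intersected with
#' `[admission + 24 h, Inf)`; stays whose window is empty contribute
#' nothing. One instance is drawn per eligible stay before any stay is
#' reused; reuse (always at a distinct reference time) happens only when
#' `target_n` cannot otherwise be met. If the pool is exhausted the result
#' is shorter than `target_n` and carries the shortfall in attribute
#' `shortfall`.
#'
#' @param stays List of `patient_stay` (or an `icu_cohort`).
#' @param target_n Number of augmented instances wanted (`>= 0`).
#' @param max_per_stay Cap on reuse of a single stay.
#' @return data.frame of instances (`stay_id`, `source`, `t_ref`, `label`
#'   = `"NRFD"`, `provenance` = `"augmented"`).
#' @export
augment_negatives <- function(stays, target_n, max_per_stay = 25L) {
  stopifnot(target_n >= 0)
  if (target_n == 0) {
    return(data.frame(stay_id = character(0), source = character(0),
                      t_ref = integer(0), label = character(0),
                      provenance = character(0), stringsAsFactors = FALSE))
  }
  iv <- t(vapply(stays, .augment_interval, numeric(2)))
  eligible <- which(iv[, "lo"] <= iv[, "hi"])
  drawn_id <- character(0); drawn_src <- character(0); drawn_t <- integer(0)
  used <- new.env(parent = emptyenv())  # stay index -> drawn t_refs
  pool <- eligible[sample.int(length(eligible))]
  round_i <- 0L
  while (length(drawn_t) < target_n && length(pool) && round_i < max_per_stay) {
    round_i <- round_i + 1L
    next_pool <- integer(0)
    for (idx in pool) {
      if (length(drawn_t) >= target_n) break
      lo <- iv[idx, "lo"]; hi <- iv[idx, "hi"]
      prev <- mget(as.character(idx), envir = used,
                   ifnotfound = list(integer(0)))[[1]]
      # draw an integer minute not used before for this stay
      avail <- (hi - lo + 1) - length(prev)
      if (avail <= 0) next
      repeat {
        t_ref <- as.integer(lo + floor(runif(1) * (hi - lo + 1)))
        t_ref <- min(t_ref, as.integer(hi))
        if (!(t_ref %in% prev)) break
      }
      assign(as.character(idx), c(prev, t_ref), envir = used)
      s <- stays[[idx]]
      drawn_id <- c(drawn_id, s$stay_id)
      drawn_src <- c(drawn_src, s$source)
      drawn_t <- c(drawn_t, t_ref)
      if (avail > 1) next_pool <- c(next_pool, idx)
    }
    pool <- next_pool
  }
  out <- data.frame(stay_id = drawn_id, source = drawn_src, t_ref = drawn_t,
                    label = rep("NRFD", length(drawn_t)),
                    provenance = rep("augmented", length(drawn_t)),
                    stringsAsFactors = FALSE)
  shortfall <- target_n - nrow(out)
  if (shortfall > 0) {
    message("augment_negatives: pool exhausted, ", shortfall,
            " instance(s) short of target")
  }
  attr(out, "shortfall") <- shortfall
  out
}

#' Build a class-balanced labelled dataset from one or more cohorts
#'
#' Labels every stay at callout, then — per source cohort — adds augmented
#' NRFD instances until the negative class matches the positive class in
#' size (or the 3–8 day sampling pool is exhausted). Every instance carries
#' its source-cohort tag for the multiple-source split machinery.
#'
#' @param cohorts A single `icu_cohort` or a list of them.
#' @return data.frame of labelled instances with attribute `stays` holding
#'   the flat list of all stays (named by `stay_id`) for feature extraction.
#' @export
#' @examples
#' coh <- generate_cohort(mimic_like_config(n_patients = 40, seed = 5))
#' d <- build_dataset(coh)
#' table(d$label, d$provenance)
build_dataset <- function(cohorts) {
  if (inherits(cohorts, "icu_cohort")) cohorts <- list(cohorts)
  if (!length(cohorts)) stop("at least one cohort is required")
  all_instances <- list()
  all_stays <- list()
  for (coh in cohorts) {
    if (!length(coh)) {
      warning("empty cohort; contributing no instances")
      next
    }
    callout <- data.table::rbindlist(lapply(coh, label_at_callout))
    n_rfd <- sum(callout$label == "RFD")
    n_nrfd <- sum(callout$label == "NRFD")
    need <- max(0L, n_rfd - n_nrfd)
    aug <- augment_negatives(coh, need)
    all_instances[[length(all_instances) + 1L]] <-
      rbind(as.data.frame(callout), aug)
    all_stays <- c(all_stays, setNames(coh, vapply(coh, `[[`, "",
                                                   "stay_id")))
  }
  out <- do.call(rbind, all_instances)
  rownames(out) <- NULL
  attr(out, "stays") <- all_stays
  out
}
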