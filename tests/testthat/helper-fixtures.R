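# Shared fixtures and independent oracles for the suite.

# cache of generated cohorts, shared across test files (generation at
# n = 5000 is the most expensive fixture; build it once)
.fixture_env <- new.env(parent = emptyenv())

cached_cohort <- function(key, builder) {
  if (is.null(.fixture_env[[key]])) .fixture_env[[key]] <- builder()
  .fixture_env[[key]]
}

big_mimic_cohort <- function() {
  cached_cohort("mimic5000", function() {
    generate_cohort(mimic_like_config(n_patients = 5000, seed = 401L))
  })
}

# Hand-built stay: every variable held at a constant in-range value on an
# hourly grid over `hours`, with optional per-variable overrides of the
# value sequence. Callout defaults to the end of the grid.
make_test_stay <- function(hours = 12, values = list(), callout = NULL,
                           discharge = NULL, died = FALSE, readmitted = FALSE,
                           id = "test-1", source = "gicu") {
  defaults <- c(airway = 1, fio2 = 0.3, spo2 = 98, hco3 = 24, resp = 16,
                bp = 120, hr = 80, pain = 0, gcs = 15, temp = 36.8,
                haemoglobin = 130, k = 4.2, na = 140, creatinine = 80,
                bun = 5)
  tt <- seq(0L, as.integer(hours * 60), by = 60L)
  series <- lapply(names(defaults), function(v) {
    val <- if (!is.null(values[[v]])) values[[v]] else
      rep(defaults[[v]], length(tt))
    if (length(val) == 1) val <- rep(val, length(tt))
    n <- min(length(val), length(tt))
    data.frame(t_minutes = tt[seq_len(n)], value = as.numeric(val[seq_len(n)]))
  })
  names(series) <- names(defaults)
  callout <- as.integer(callout %||% max(tt))
  structure(list(
    stay_id = id, source = source,
    admission_time = 0L, callout_time = callout,
    icu_discharge_time = as.integer(discharge %||% max(callout, max(tt))),
    age = 60, sex = 0, bmi = 25,
    died_in_hospital = died, readmitted = readmitted,
    series = series
  ), class = "patient_stay")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Brute-force pairwise AUROC oracle: concordant-pair probability with ties
# counted half. Independent of the threshold-sweep implementation.
pairwise_auroc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + (p > q) + 0.5 * (p == q)
  }
  tot / (length(pos) * length(neg))
}

# Brute-force nan-aware kNN imputation oracle for small matrices.
knn_impute_oracle <- function(X, k) {
  p <- ncol(X)
  mu <- colMeans(X, na.rm = TRUE)
  sdev <- apply(X, 2, sd, na.rm = TRUE)
  sdev[!is.finite(sdev) | sdev == 0] <- 1
  Z <- sweep(sweep(X, 2, mu, "-"), 2, sdev, "/")
  out <- X
  for (i in seq_len(nrow(X))) for (f in seq_len(p)) {
    if (!is.na(X[i, f])) next
    d <- rep(Inf, nrow(X))
    for (j in seq_len(nrow(X))) {
      if (j == i || is.na(X[j, f])) next
      mutual <- which(!is.na(Z[i, ]) & !is.na(Z[j, ]))
      if (!length(mutual)) next
      d[j] <- sum((Z[i, mutual] - Z[j, mutual])^2) * p / length(mutual)
    }
    cand <- order(d, seq_along(d))
    cand <- cand[is.finite(d[cand])]
    nn <- head(cand, k)
    out[i, f] <- if (length(nn)) mean(X[nn, f]) else mu[f]
  }
  out
}

# Random labelled dataset of discharge-test counts, for NLD/ROC properties.
random_count_dataset <- function(n) {
  repeat {
    y <- rbinom(n, 1, 0.5)
    if (length(unique(y)) == 2) break
  }
  list(counts = sample(0:15, n, replace = TRUE), labels = y)
}
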