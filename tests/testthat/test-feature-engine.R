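test_that("window aggregation takes the stated extremes and recency", {
  hr <- c(rep(80, 10), 55, 80, 101)   # last three inside the 4 h window
  stay <- make_test_stay(hours = 12, values = list(hr = hr))
  f <- extract_features(stay, t_ref = 12 * 60)
  expect_equal(f[["hr_min"]], 55)
  expect_equal(f[["hr_max"]], 101)
  expect_equal(sum(is.na(f)), 0)
  expect_length(f, 18)
  expect_length(extract_features(stay, 12 * 60, extended = TRUE), 22)
})

test_that("empty 4 h window falls back to 36 h; absent after that is NA", {
  stay <- make_test_stay(hours = 24)
  # single bicarbonate draw 20 h before the reference time
  stay$series$hco3 <- data.frame(t_minutes = 4 * 60, value = 22)
  f <- extract_features(stay, t_ref = 24 * 60)
  expect_equal(f[["hco3"]], 22)

  # nothing within 36 h
  stay$series$bun <- data.frame(t_minutes = integer(0), value = numeric(0))
  f2 <- extract_features(stay, t_ref = 24 * 60)
  expect_true(is.na(f2[["bun"]]))

  # labs use the most recent draw, not an extreme
  stay$series$k <- data.frame(t_minutes = c(21, 22, 23) * 60,
                              value = c(9, 2, 4.4))
  f3 <- extract_features(stay, t_ref = 24 * 60)
  expect_equal(f3[["k"]], 4.4)
})

test_that("the window is half-open: (t_ref - w, t_ref]", {
  stay <- make_test_stay(hours = 8)
  stay$series$hr <- data.frame(t_minutes = c(4 * 60, 8 * 60),
                               value = c(150, 70))
  f <- extract_features(stay, t_ref = 8 * 60)
  # the observation exactly at t_ref - 4 h is excluded, at t_ref included
  expect_equal(f[["hr_min"]], 70)
  expect_equal(f[["hr_max"]], 70)
  expect_error(extract_features(stay, t_ref = -10), "precedes admission")
})

test_that("fallback triggers iff the short window is empty", {
  stay <- make_test_stay(hours = 24)
  stay$series$hr <- data.frame(t_minutes = c(2 * 60, 23 * 60),
                               value = c(140, 75))
  f <- extract_features(stay, t_ref = 24 * 60)
  # short window non-empty: the 36 h value at 2 h must NOT contribute
  expect_equal(f[["hr_max"]], 75)
})

test_that("kNN imputation matches the brute-force oracle", {
  set.seed(44)
  X <- matrix(rnorm(20 * 6), 20, 6,
              dimnames = list(NULL, paste0("f", 1:6)))
  expect_identical(knn_impute(X, 3), X)   # nothing to do

  holes <- cbind(sample(1:20, 8), sample(1:6, 8, replace = TRUE))
  Xm <- X; Xm[holes] <- NA
  for (k in c(1, 3, 5)) {
    got <- knn_impute(Xm, k)
    want <- knn_impute_oracle(Xm, k)
    expect_equal(got, want)
    # observed cells untouched; imputed cells inside the observed range
    expect_identical(got[!is.na(Xm)], Xm[!is.na(Xm)])
    for (j in unique(holes[, 2])) {
      rng <- range(Xm[, j], na.rm = TRUE)
      miss <- is.na(Xm[, j])
      expect_true(all(got[miss, j] >= rng[1] & got[miss, j] <= rng[2]))
    }
  }

  # exact duplicate rows: k = 1 copies the duplicate's value
  Xd <- rbind(c(1, 2, 3), c(1, 2, NA), c(50, 60, 70))
  colnames(Xd) <- paste0("f", 1:3)
  expect_equal(unname(knn_impute(Xd, 1)[2, 3]), 3)

  Xbad <- Xm; Xbad[, 2] <- NA
  colnames(Xbad) <- paste0("f", 1:6)
  expect_error(knn_impute(Xbad, 3), "f2")
})

test_that("standardisation fits on training data only", {
  tr <- cbind(a = c(1, 2, 3), b = c(5, 5, 5))
  te <- cbind(a = c(2, 4), b = c(7, 9))
  out <- standardise(tr, test = te)
  expect_equal(out$train[, "a"], c(-1, 0, 1))
  expect_equal(out$train[, "b"], c(0, 0, 0))     # zero-variance policy
  expect_equal(out$test[, "a"], c(0, 2))         # (x - 2) / 1
  expect_equal(out$test[, "b"], c(0, 0))
  expect_equal(unname(out$center), c(2, 5))

  big <- matrix(rnorm(200), 50, 4)
  z <- standardise(big)$train
  expect_equal(unname(colMeans(z)), rep(0, 4))
  expect_equal(unname(apply(z, 2, sd)), rep(1, 4))
  expect_error(standardise(matrix(numeric(0), 0, 3)), "empty")
})

test_that("feature matrices have the canonical shape", {
  coh <- generate_cohort(gicu_like_config(n_patients = 10, seed = 71))
  d <- build_dataset(coh)
  X <- build_feature_matrix(d)
  expect_equal(dim(X), c(nrow(d), 18))
  expect_identical(colnames(X), icuready:::.base_features)
  Xe <- build_feature_matrix(d, extended = TRUE)
  expect_equal(ncol(Xe), 22)
  expect_false(anyNA(Xe[, c("age", "sex", "bmi", "hours_since_admission")]))
})
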