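test_that("codified tests evaluate inclusively at their printed bounds", {
  f <- boundary_feature_vector()
  res <- evaluate_tests(f)
  expect_equal(res$n_passed, 15)
  expect_length(res$tests_with_missing_inputs, 0)

  # coma-score bound: 14 passes, 13 fails
  f2 <- f; f2["gcs_min"] <- 14
  expect_true(evaluate_tests(f2)$passed[["CNS"]])
  f2["gcs_min"] <- 13
  expect_false(evaluate_tests(f2)$passed[["CNS"]])

  # inspired oxygen exactly at the cap is acceptable
  f3 <- f; f3["fio2"] <- 0.6
  expect_true(evaluate_tests(f3)$passed[["R1"]])

  # heart-rate pair: lower-bound violation on the window minimum
  f4 <- f; f4["hr_min"] <- 59; f4["hr_max"] <- 100
  expect_false(evaluate_tests(f4)$passed[["C1"]])
})

test_that("missing inputs fail conservatively and are recorded", {
  f <- boundary_feature_vector()
  f["bun"] <- NA
  res <- evaluate_tests(f)
  expect_equal(res$n_passed, 14)
  expect_identical(res$tests_with_missing_inputs, "B4")
})

test_that("threshold overrides and validation", {
  th <- nld_thresholds(list(CNS = c(lower = 13)))
  expect_equal(th$lower[th$test_id == "CNS"], 13)
  expect_error(nld_thresholds(list(T = c(lower = 39, upper = 37.5))),
               "inverted")
  expect_error(nld_thresholds(list(ZZ = c(lower = 1))), "unknown test")
})

test_that("thresholds round-trip through YAML and JSON", {
  th <- nld_thresholds()
  for (ext in c("yaml", "json")) {
    path <- tempfile(fileext = paste0(".", ext))
    write_thresholds(th, path)
    back <- read_thresholds(path)
    expect_equal(as.data.frame(back), as.data.frame(th))
  }
})

test_that("count score takes the 16 lattice values and weighting reduces to it", {
  f <- boundary_feature_vector()
  expect_equal(nld_score(evaluate_tests(f)), 1.0)
  # push every test out of bounds on its closed side
  th <- nld_thresholds()
  fmap <- icuready:::.test_features()
  f0 <- f
  for (id in th$test_id) {
    i <- match(id, th$test_id)
    feats <- fmap[[id]]
    if (!is.na(th$lower[i])) {
      f0[feats[1]] <- th$lower[i] - 0.5
    } else {
      f0[feats[length(feats)]] <- th$upper[i] + 0.5
    }
  }
  expect_equal(nld_score(evaluate_tests(f0)), 0.0)

  uniform <- setNames(rep(1 / 15, 15), names(evaluate_tests(f)$passed))
  set.seed(202)
  for (i in 1:400) {
    pattern <- rbinom(15, 1, runif(1)) == 1
    res <- structure(list(passed = setNames(pattern, names(uniform)),
                          n_passed = sum(pattern),
                          tests_with_missing_inputs = character(0)),
                     class = "criteria_result")
    expect_equal(nld_score(res), sum(pattern) / 15)
    expect_equal(weighted_score(res, uniform), nld_score(res))
    expect_true(nld_score(res) %in% (0:15 / 15))
  }
})

test_that("flipping a test to pass never decreases either score", {
  set.seed(99)
  ids <- nld_thresholds()$test_id
  w <- runif(15); w <- setNames(w / sum(w), ids)
  for (i in 1:100) {
    pattern <- rbinom(15, 1, 0.5) == 1
    fails <- which(!pattern)
    if (!length(fails)) next
    res <- structure(list(passed = setNames(pattern, ids),
                          n_passed = sum(pattern),
                          tests_with_missing_inputs = character(0)),
                     class = "criteria_result")
    j <- sample(fails, 1)
    flipped <- pattern; flipped[j] <- TRUE
    res2 <- structure(list(passed = setNames(flipped, ids),
                           n_passed = sum(flipped),
                           tests_with_missing_inputs = character(0)),
                      class = "criteria_result")
    expect_gte(nld_score(res2), nld_score(res))
    expect_gte(weighted_score(res2, w), weighted_score(res, w))
  }
})

test_that("importance-to-weight mapping aggregates constituent features", {
  base <- setNames(rep(1, 18), names(boundary_feature_vector()))
  w <- weights_from_importance(base)
  # symmetric importances: paired tests get twice the weight of single ones
  expect_equal(sum(w), 1)
  expect_equal(w[["R4"]], 2 * w[["R1"]])

  conc <- base * 0; conc["gcs_min"] <- 5
  expect_equal(weights_from_importance(conc)[["CNS"]], 1)

  # two-feature aggregation, by hand: C1 = (imp_hr_min + imp_hr_max) / total
  imp <- base * 0
  imp[c("hr_min", "hr_max", "bun")] <- c(0.2, 0.3, 0.5)
  w2 <- weights_from_importance(imp)
  expect_equal(w2[["C1"]], 0.5)
  expect_equal(w2[["B4"]], 0.5)

  # negative importances are floored, missing features are an error
  imp2 <- base; imp2["pain"] <- -3
  expect_equal(weights_from_importance(imp2)[["P"]], 0)
  expect_error(weights_from_importance(base[-1]), "airway")
  expect_error(weighted_score(evaluate_tests(boundary_feature_vector()),
                              setNames(c(-1, rep(2 / 14, 14)),
                                       nld_thresholds()$test_id)),
               "negative")
})

test_that("sustained readiness requires all tests over the whole window", {
  ok <- make_test_stay(hours = 12)
  expect_true(sustained_rfd(ok, at_time = 12 * 60))

  # a single heart-rate violation one hour before the reference time
  hr <- rep(80, 13); hr[12] <- 130   # t = 11 h = 1 h before at_time
  bad <- make_test_stay(hours = 12, values = list(hr = hr))
  expect_false(sustained_rfd(bad, at_time = 12 * 60))
  expect_true(sustained_rfd(bad, at_time = 12 * 60, window_hours = 0.5))

  # a variable absent from the window fails its test as missing-input
  sparse <- make_test_stay(hours = 12)
  sparse$series$bun <- data.frame(t_minutes = integer(0), value = numeric(0))
  flag <- sustained_rfd(sparse, at_time = 12 * 60)
  expect_false(flag)
  expect_identical(attr(flag, "result")$tests_with_missing_inputs, "B4")

  expect_error(sustained_rfd(ok, at_time = 10000), "outside")
})
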