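test_that("roc_curve and auroc handle separation, ties and known cases", {
  # perfect separation
  expect_equal(auroc(c(0.9, 0.8, 0.4, 0.3), c(1, 1, 0, 0)), 1.0)
  # 3 of 4 concordant pairs (oracle: pairwise count)
  expect_equal(auroc(c(0.9, 0.8, 0.6, 0.4), c(1, 0, 1, 0)), 0.75)
  expect_equal(pairwise_auroc(c(0.9, 0.8, 0.6, 0.4), c(1, 0, 1, 0)), 0.75)
  # uninformative scorer
  expect_equal(auroc(rep(0.5, 6), c(1, 0, 1, 0, 1, 0)), 0.5)
  expect_error(roc_curve(c(1, 2), c(1, 1)), "both classes")

  roc <- roc_curve(c(0.9, 0.8, 0.6, 0.4), c(1, 0, 1, 0))
  expect_equal(roc$fpr[1], 0)
  expect_equal(roc$tpr[1], 0)
  expect_equal(utils::tail(roc$fpr, 1), 1)
  expect_equal(utils::tail(roc$tpr, 1), 1)
  expect_true(all(diff(roc$fpr) >= 0) && all(diff(roc$tpr) >= 0))
})

test_that("auroc equals the pairwise concordance oracle on small inputs", {
  set.seed(42)
  for (rep_i in 1:200) {
    n <- sample(2:12, 1)
    y <- c(0, 1, rbinom(max(0, n - 2), 1, 0.5))[seq_len(max(n, 2))]
    s <- sample(seq(0, 1, by = 0.1), length(y), replace = TRUE)
    expect_equal(auroc(s, y), pairwise_auroc(s, y))
  }
})

test_that("pauroc limits, interpolation and monotonicity", {
  perfect <- roc_curve(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))
  expect_equal(pauroc(perfect, 0.3), 0.3)
  # constant scores trace the chance diagonal: area over [0, .3] is .3^2/2
  diag <- roc_curve(rep(0.5, 10), rep(c(0, 1), 5))
  expect_equal(pauroc(diag, 0.3), 0.045)

  set.seed(7)
  s <- runif(40); y <- rbinom(40, 1, 0.5); y[1:2] <- c(0, 1)
  roc <- roc_curve(s, y)
  expect_equal(pauroc(roc, 1), auroc(roc))
  grid <- seq(0.05, 1, by = 0.05)
  vals <- vapply(grid, function(m) pauroc(roc, m), numeric(1))
  expect_true(all(diff(vals) >= -1e-12))
  expect_error(pauroc(roc, 0), "max_fpr")
  expect_error(pauroc(roc, 1.2), "max_fpr")
})

test_that("operating point interpolates sensitivity at the target specificity", {
  # between curve points (0.2, 0.6) and (0.4, 0.9) at fpr 0.3
  roc <- structure(
    data.frame(fpr = c(0, 0.2, 0.4, 1), tpr = c(0, 0.6, 0.9, 1),
               threshold = c(Inf, 0.8, 0.5, 0.1)),
    class = c("roc_curve", "data.frame"))
  op <- operating_point(roc, specificity = 0.7)
  expect_equal(op$sensitivity, 0.75)
  expect_identical(op$specificity, 0.7)

  # a point exactly on the grid is returned unchanged
  roc2 <- structure(
    data.frame(fpr = c(0, 0.3, 1), tpr = c(0, 0.65, 1),
               threshold = c(Inf, 0.6, 0.1)),
    class = c("roc_curve", "data.frame"))
  expect_equal(operating_point(roc2, 0.7)$sensitivity, 0.65)

  # a perfect classifier is fully sensitive at any specificity
  perfect <- roc_curve(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))
  expect_equal(operating_point(perfect, 0.7)$sensitivity, 1.0)
  expect_equal(operating_point(perfect, 0.95)$sensitivity, 1.0)
})

test_that("brier score matches hand computations and prevalence optimality", {
  expect_equal(brier(rep(0.5, 4), c(1, 0, 1, 0)), 0.25)
  expect_equal(brier(c(1, 0, 1), c(1, 0, 1)), 0)
  expect_equal(brier(c(0.8, 0.2), c(1, 0)), 0.04)
  expect_error(brier(numeric(0), numeric(0)), "empty")

  set.seed(11)
  y <- rbinom(300, 1, 0.3)
  prev <- mean(y)
  b_at_prev <- brier(rep(prev, 300), y)
  for (c0 in seq(0.05, 0.95, by = 0.05)) {
    expect_gte(brier(rep(c0, 300), y), b_at_prev - 1e-12)
  }
})

test_that("spearman_rank: extremes, errors, and the printed-rank oracle", {
  expect_equal(spearman_rank(1:10, 1:10), 1.0)
  expect_equal(spearman_rank(1:10, 10:1), -1.0)
  expect_error(spearman_rank(1:3, 1:4), "equal length")

  # published feature rankings of the two classifier families (18 features,
  # dense ranks 0..17); oracle: the classical d^2 formula for tie-free ranks
  lc_rank <- c(0, 1, 2, 3, 4, 5, 6, 7, 8, 9, 10, 11, 12, 13, 14, 15, 16, 17)
  rf_rank <- c(0, 1, 3, 2, 4, 6, 7, 5, 15, 14, 16, 11, 9, 13, 8, 17, 12, 10)
  n <- 18
  rho_oracle <- 1 - 6 * sum((lc_rank - rf_rank)^2) / (n * (n^2 - 1))
  expect_equal(spearman_rank(lc_rank, rf_rank), rho_oracle)
  expect_equal(round(rho_oracle, 3), 0.761)
})

test_that("metric_report assembles the suite with fractional confusion", {
  set.seed(3)
  y <- rbinom(200, 1, 0.5); y[1:2] <- c(0, 1)
  s <- plogis(rnorm(200) + 2 * y)
  rep <- metric_report(s, y)
  expect_named(rep, c("auroc", "pauroc", "accuracy", "f1", "specificity",
                      "sensitivity", "brier"), ignore.order = TRUE)
  expect_true(all(unlist(rep) >= 0 & unlist(rep) <= 1))
  expect_identical(rep$specificity, 0.7)
  expect_lte(rep$pauroc, 0.3)
  # accuracy identity at the interpolated point
  p <- mean(y)
  expect_equal(rep$accuracy, p * rep$sensitivity + (1 - p) * 0.7)
})
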