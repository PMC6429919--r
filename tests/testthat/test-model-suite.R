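test_that("multiple-source split sizes follow the 30%/equal-size rule", {
  src <- c(rep("gicu", 100), rep("mimic", 400))
  set.seed(1)
  sp <- multisource_split(src)
  expect_length(sp$test$gicu, 30)
  expect_length(sp$test$mimic, 30)
  expect_length(sp$train, 440)
  # disjoint, and both sources present on each side
  expect_length(intersect(sp$train, unlist(sp$test)), 0)
  expect_setequal(unique(src[sp$train]), c("gicu", "mimic"))
  expect_true(all(src[sp$test$gicu] == "gicu"))
  expect_true(all(src[sp$test$mimic] == "mimic"))

  # rounding to the nearest instance
  sp2 <- multisource_split(c(rep("gicu", 10), rep("mimic", 50)))
  expect_length(sp2$test$gicu, 3)
  expect_length(sp2$test$mimic, 3)

  expect_error(multisource_split(rep("gicu", 50)), "two sources")
  expect_error(multisource_split(c(rep("gicu", 100), rep("mimic", 20))),
               "smaller than the required test size")
})

test_that("two-fold multiple-source CV selects by fold-mean AUROC", {
  set.seed(23)
  n <- 300
  x1 <- rnorm(n); x2 <- rnorm(n)
  y <- rbinom(n, 1, plogis(2.5 * x1))
  X <- cbind(signal = x1, noise = x2)
  src <- rep(c("gicu", "mimic"), each = n / 2)

  # grid of one: returned as-is
  one <- tune_multisource_cv(X, y, src, "logistic",
                             list(list(lambda = 0.01)))
  expect_equal(one$params$lambda, 0.01)

  # a constant scorer (unsplittable forest) scores exactly 0.5 and never
  # beats a discriminating grid point
  grid <- list(list(ntree = 5, max_depth = 1, min_leaf = 10 * n),
               list(ntree = 30, max_depth = 6, min_leaf = 5))
  tuned <- tune_multisource_cv(X, y, src, "forest", grid)
  expect_equal(tuned$scores[1], 0.5)
  expect_identical(tuned$params, grid[[2]])

  # exhaustive verification: the winner's fold-mean beats every grid point,
  # recomputed independently of the tuner
  lgrid <- lapply(10^seq(0, -4), function(l) list(lambda = l))
  tl <- tune_multisource_cv(X, y, src, "logistic", lgrid)
  folds <- list(which(src == "gicu"), which(src == "mimic"))
  manual <- vapply(lgrid, function(params) {
    mean(vapply(1:2, function(i) {
      fit <- fit_classifier(X[folds[[i]], ], y[folds[[i]]], "logistic",
                            params)
      auroc(predict_prob(fit, X[folds[[3 - i]], ]), y[folds[[3 - i]]])
    }, numeric(1)))
  }, numeric(1))
  expect_equal(tl$scores, manual)
  expect_true(all(max(manual) - manual >= -1e-12))
  expect_equal(tl$cv_auroc, max(manual))

  # degenerate single-class fold
  ybad <- y; ybad[src == "gicu"] <- 1
  expect_error(tune_multisource_cv(X, ybad, src, "logistic", lgrid),
               "degenerate fold")
  expect_error(tune_multisource_cv(X, y, src, "logistic", list()), "empty")
})

test_that("fitted classifiers behave at the extremes", {
  # linearly separable toy data
  X <- cbind(x = c(-3, -2, -1, 1, 2, 3), z = rep(0, 6))
  y <- c(0, 0, 0, 1, 1, 1)
  lc <- suppressWarnings(   # glmnet warns on tiny class counts
    fit_classifier(X, y, "logistic", list(lambda = 1e-4)))
  expect_equal(auroc(predict_prob(lc, X), y), 1.0)
  expect_error(fit_classifier(X, rep(1, 6), "logistic"), "single-class")

  # a fitted model scores identical instances identically
  set.seed(31)
  Xr <- matrix(rnorm(600), 100, 6); yr <- rbinom(100, 1, 0.5)
  yr[1:2] <- c(0, 1)
  rf <- fit_classifier(Xr, yr, "forest", list(ntree = 20))
  two <- predict_prob(rf, Xr[c(7, 7), , drop = FALSE])
  expect_identical(two[1], two[2])

  # labels independent of features: held-out AUROC hovers near chance
  set.seed(32)
  Xn <- matrix(rnorm(4000), 1000, 4); yn <- rbinom(1000, 1, 0.5)
  lcn <- fit_classifier(Xn[1:500, ], yn[1:500], "logistic",
                        list(lambda = 1e-2))
  a <- auroc(predict_prob(lcn, Xn[501:1000, ]), yn[501:1000])
  expect_lt(abs(a - 0.5), 0.1)
})

test_that("permutation importance isolates predictive features", {
  set.seed(53)
  n <- 400
  strong <- rnorm(n)
  X <- cbind(strong = strong, noise1 = rnorm(n), noise2 = rnorm(n))
  y <- as.integer(strong + rnorm(n, 0, 0.3) > 0)
  lc <- fit_classifier(X, y, "logistic", list(lambda = 1e-3))

  expect_error(permutation_importance(lc, X, y, n_repeats = 0), "n_repeats")

  # forcing the identity permutation gives exactly zero importance
  imp0 <- permutation_importance(lc, X, y, n_repeats = 2,
                                 perm_fun = function(n) seq_len(n))
  expect_identical(unname(imp0), rep(0, 3))

  imp <- permutation_importance(lc, X, y, n_repeats = 10)
  expect_equal(names(which.max(imp)), "strong")
  expect_gt(imp[["strong"]], 0.2)
  # null features score near zero
  expect_lt(max(abs(imp[c("noise1", "noise2")])), 0.05)
})

test_that("run_experiment is reproducible and aggregates correctly", {
  m <- generate_cohort(mimic_like_config(n_patients = 120, seed = 81))
  g <- generate_cohort(gicu_like_config(n_patients = 60, seed = 82))
  d <- build_dataset(list(m, g))
  X <- knn_impute(build_feature_matrix(d))
  y <- as.integer(d$label == "RFD")
  grids <- list(logistic = list(list(lambda = 1e-2)),
                forest = list(list(ntree = 20, max_depth = 6, min_leaf = 5)))

  r1 <- run_experiment(X, y, d$source, n_splits = 2, seed = 9, grids = grids,
                       importance_repeats = 2)
  r2 <- run_experiment(X, y, d$source, n_splits = 2, seed = 9, grids = grids,
                       importance_repeats = 2)
  expect_identical(r1$summary, r2$summary)
  expect_identical(r1$importance_summary, r2$importance_summary)

  # shape: 4 systems x 2 cohorts x 7 metrics x 2 splits
  expect_equal(nrow(r1$per_split), 4 * 2 * 7 * 2)
  expect_true(all(r1$per_split$value >= 0 & r1$per_split$value <= 1))
  expect_true(!is.null(r1$spearman) &&
                abs(r1$spearman) <= 1)
  # dense ranks start at 0 within each family
  for (fam in unique(r1$importance_summary$family)) {
    expect_equal(min(r1$importance_summary$rank[
      r1$importance_summary$family == fam]), 0)
  }

  # single split: SDs reported as zero by convention and flagged
  r3 <- run_experiment(X, y, d$source, systems = c("logistic"),
                       n_splits = 1, seed = 9, grids = grids,
                       importance_repeats = 2)
  expect_true(r3$single_split)
  expect_true(all(r3$summary$sd == 0))
})
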