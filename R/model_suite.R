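#' Specify the multiple-source train/test split
#'
#' One source cohort (the smaller, `primary`) holds out `test_fraction` of
#' its instances for testing; every other source holds out a test set of
#' the *same absolute size*, sampled without replacement. The remainder of
#' both sources is pooled for training, so both populations are represented
#' on each side of the split.
#'
#' @param test_fraction Fraction of the primary source held out (default
#'   0.30, rounded to the nearest instance).
#' @param primary Label of the primary source cohort (default `"gicu"`).
#' @return Object of class `split_spec`.
#' @export
split_spec <- function(test_fraction = 0.30, primary = "gicu") {
  stopifnot(test_fraction > 0, test_fraction < 1)
  structure(list(test_fraction = test_fraction, primary = primary),
            class = "split_spec")
}

#' Draw one multiple-source train/test split
#'
#' @param source Character vector of source labels, one per instance.
#' @param spec A [split_spec()].
#' @return List with `train` (integer indices, pooled) and `test` (named
#'   list of per-source index vectors).
#' @export
multisource_split <- function(source, spec = split_spec()) {
  labels <- unique(source)
  if (length(labels) < 2) stop("dataset must contain at least two sources")
  if (!spec$primary %in% labels) {
    stop("primary source '", spec$primary, "' absent from the dataset")
  }
  idx_primary <- which(source == spec$primary)
  n_test <- round(spec$test_fraction * length(idx_primary))
  if (n_test < 1) stop("primary source too small for a test set")
  test <- list()
  test[[spec$primary]] <- sort(sample(idx_primary, n_test))
  for (s in setdiff(labels, spec$primary)) {
    idx_s <- which(source == s)
    if (length(idx_s) <= n_test) {
      stop("source '", s, "' smaller than the required test size ", n_test)
    }
    test[[s]] <- sort(sample(idx_s, n_test))
  }
  train <- setdiff(seq_along(source), unlist(test))
  list(train = train, test = test)
}

#' Default hyperparameter grids
#'
#' Logistic: ridge penalty over a log-spaced grid, ordered strongest-first
#' so ties resolve toward the simpler model. Forest: tree depth and leaf
#' size over a small grid, shallow-first, with tree count fixed.
#'
#' @param ntree Trees per forest grid point.
#' @return Named list of per-family lists of parameter lists.
#' @export
default_grids <- function(ntree = 60L) {
  list(
    logistic = lapply(10^seq(0, -4), function(l) list(lambda = l)),
    forest = list(
      list(ntree = ntree, max_depth = 4L, min_leaf = 10L),
      list(ntree = ntree, max_depth = 8L, min_leaf = 5L),
      list(ntree = ntree, max_depth = 12L, min_leaf = 2L)
    )
  )
}

#' Tune hyperparameters by two-fold multiple-source cross-validation
#'
#' For each grid point the model is fitted on the fold drawn entirely from
#' one source and scored (AUROC) on the fold from the other, in both
#' directions; the grid point maximising the two-fold mean AUROC wins.
#' Ties go to the earlier grid entry, so grids ordered simple-to-complex
#' resolve ties toward the simpler model.
#'
#' @param X,y Training matrix and binary labels.
#' @param source Source label per training instance (exactly two sources).
#' @param family `"logistic"` or `"forest"`.
#' @param grid List of hyperparameter lists (non-empty).
#' @return List: `params` (winning grid point), `cv_auroc` (its fold-mean),
#'   `scores` (fold-mean AUROC per grid point).
#' @export
tune_multisource_cv <- function(X, y, source, family, grid) {
  if (!length(grid)) stop("empty hyperparameter grid")
  y <- .as_binary(y)
  labels <- unique(source)
  if (length(labels) != 2) stop("training data must contain two sources")
  folds <- lapply(labels, function(s) which(source == s))
  for (f in folds) {
    if (length(unique(y[f])) < 2) {
      stop("degenerate fold: source with a single class")
    }
  }
  scores <- vapply(grid, function(params) {
    a <- vapply(1:2, function(i) {
      fit <- fit_classifier(X[folds[[i]], , drop = FALSE], y[folds[[i]]],
                            family, params)
      auroc(predict_prob(fit, X[folds[[3 - i]], , drop = FALSE]),
            y[folds[[3 - i]]])
    }, numeric(1))
    mean(a)
  }, numeric(1))
  best <- which(scores >= max(scores) - 1e-12)[1]
  list(params = grid[[best]], cv_auroc = scores[best], scores = scores)
}

#' Retrain the tuned model on the full training data
#'
#' Thin wrapper over [fit_classifier()] marking the protocol step where the
#' optimised classifier is refitted on the pooled multi-source training set.
#'
#' @inheritParams fit_classifier
#' @param params Tuned hyperparameters from [tune_multisource_cv()].
#' @return An `rfd_model`.
#' @export
fit_final <- function(X, y, family, params) {
  fit_classifier(X, y, family, params)
}

#' Permutation feature importance
#'
#' Importance of feature f = mean over `n_repeats` independent permutations
#' of (baseline AUROC - AUROC with column f permuted). Features the model
#' ignores score about 0; features carrying unique signal score up to the
#' baseline's margin over chance.
#'
#' @param model A fitted `rfd_model`.
#' @param X,y Evaluation matrix and labels (typically held-out data).
#' @param n_repeats Permutations per feature (`>= 1`).
#' @param perm_fun Permutation generator `function(n)`; the default draws a
#'   uniform random permutation (exposed so that degenerate permutations can
#'   be forced in tests).
#' @return Named numeric vector of importances, one per column of `X`.
#' @export
permutation_importance <- function(model, X, y, n_repeats = 5,
                                   perm_fun = sample.int) {
  if (n_repeats < 1) stop("n_repeats must be at least 1")
  y <- .as_binary(y)
  baseline <- auroc(predict_prob(model, X), y)
  n <- nrow(X)
  imp <- setNames(numeric(ncol(X)), colnames(X))
  for (f in seq_len(ncol(X))) {
    drop_f <- vapply(seq_len(n_repeats), function(r) {
      Xp <- X
      Xp[, f] <- X[perm_fun(n), f]
      baseline - auroc(predict_prob(model, Xp), y)
    }, numeric(1))
    imp[f] <- mean(drop_f)
  }
  imp
}

# Vectorised pass matrix: one row per instance, one column per test.
.pass_matrix <- function(X, thresholds = nld_thresholds()) {
  fmap <- .test_features()
  out <- matrix(FALSE, nrow(X), length(.test_ids),
                dimnames = list(NULL, .test_ids))
  for (id in .test_ids) {
    i <- match(id, thresholds$test_id)
    lo <- thresholds$lower[i]; hi <- thresholds$upper[i]
    feats <- fmap[[id]]
    if (length(feats) == 2) {
      ok <- X[, feats[1]] >= lo & X[, feats[2]] <= hi
    } else {
      x <- X[, feats]
      ok <- rep(TRUE, nrow(X))
      if (!is.na(lo)) ok <- ok & x >= lo
      if (!is.na(hi)) ok <- ok & x <= hi
    }
    ok[is.na(ok)] <- FALSE      # missing-as-fail
    out[, id] <- ok
  }
  out
}

#' Run the full repeated-split classification experiment
#'
#' One iteration: draw a multiple-source split, standardise features on the
#' training pool, tune each classifier family by two-fold multiple-source
#' CV, retrain on the full training pool, evaluate the metric suite on each
#' per-source test set, and compute permutation importances on the pooled
#' test data. Rule-based systems are evaluated on the same splits: `"nld"`
#' scores each test instance by its fraction of discharge tests passed
#' (on the raw, unstandardised features), and `"nld_weighted"` reweights
#' the tests by the logistic classifier's permutation importances from the
#' same split. The whole procedure repeats over `n_splits` random splits;
#' reported metrics are the per-cohort mean and SD across splits.
#'
#' @param X Imputed (unstandardised) feature matrix; its first 18 columns
#'   must be the base features when NLD systems are requested.
#' @param y Binary labels (1 = RFD).
#' @param source Source label per instance.
#' @param systems Subset of `c("nld", "nld_weighted", "logistic",
#'   "forest")`.
#' @param n_splits Number of random train/test splits (default 100).
#' @param seed Master seed; child seeds drive each split, tune, fit and
#'   permutation, making the whole experiment reproducible.
#' @param grids See [default_grids()].
#' @param spec A [split_spec()].
#' @param thresholds An [nld_thresholds()] table for the rule-based systems.
#' @param importance_repeats Permutations per feature and split.
#' @param store_scores Keep per-instance test scores of the first split
#'   (for ROC/PRC curve exports).
#' @return Object of class `experiment_result`: `per_split` and `summary`
#'   tidy metric tables, `importance` and `importance_summary` (with dense
#'   ranks, 0 = most important), `spearman` (rank agreement between the two
#'   families' mean-importance rankings, when both were run), and
#'   optionally `first_split_scores`.
#' @export
run_experiment <- function(X, y, source,
                           systems = c("nld", "nld_weighted", "logistic",
                                       "forest"),
                           n_splits = 100, seed = 1, grids = default_grids(),
                           spec = split_spec(), thresholds = nld_thresholds(),
                           importance_repeats = 5, store_scores = TRUE) {
  stopifnot(n_splits >= 1)
  systems <- match.arg(systems, several.ok = TRUE)
  y <- .as_binary(y)
  families <- intersect(c("logistic", "forest"), systems)
  need_logistic <- "nld_weighted" %in% systems || "logistic" %in% systems

  old_seed <- .save_rng()
  on.exit(.restore_rng(old_seed), add = TRUE)
  set.seed(seed)
  child <- sample.int(.Machine$integer.max - 1L, n_splits)

  pass_mat <- if (any(c("nld", "nld_weighted") %in% systems)) {
    .pass_matrix(X[, .base_features, drop = FALSE], thresholds)
  }

  metric_rows <- vector("list", n_splits)
  importance_rows <- vector("list", n_splits)
  first_scores <- NULL

  for (s in seq_len(n_splits)) {
    res <- tryCatch(
      .run_one_split(X, y, source, systems, families, need_logistic,
                     grids, spec, thresholds, pass_mat,
                     importance_repeats, child[s],
                     keep_scores = store_scores && s == 1L),
      error = function(e) stop("split ", s, ": ", conditionMessage(e),
                               call. = FALSE)
    )
    res$metrics$split <- s
    metric_rows[[s]] <- res$metrics
    if (!is.null(res$importance)) {
      res$importance$split <- s
      importance_rows[[s]] <- res$importance
    }
    if (!is.null(res$scores)) first_scores <- res$scores
  }

  per_split <- data.table::rbindlist(metric_rows)
  sd0 <- function(v) if (length(v) > 1) sd(v) else 0
  summary <- per_split[, list(mean = mean(value), sd = sd0(value)),
                       by = c("cohort", "system", "metric")]

  importance <- if (length(importance_rows) && !is.null(importance_rows[[1]]))
    data.table::rbindlist(importance_rows) else NULL
  importance_summary <- NULL
  spearman <- NULL
  if (!is.null(importance)) {
    importance_summary <- importance[, list(mean = mean(importance),
                                            sd = sd0(importance)),
                                     by = c("family", "feature")]
    importance_summary[, "rank" := as.integer(
      data.table::frank(-mean, ties.method = "min") - 1L), by = "family"]
    fams <- unique(importance_summary$family)
    if (length(fams) == 2) {
      a <- importance_summary[importance_summary$family == fams[1], ]
      b <- importance_summary[importance_summary$family == fams[2], ]
      b <- b[match(a$feature, b$feature), ]
      spearman <- spearman_rank(a$mean, b$mean)
    }
  }

  structure(list(
    per_split = as.data.frame(per_split),
    summary = as.data.frame(summary),
    importance = if (!is.null(importance)) as.data.frame(importance),
    importance_summary = if (!is.null(importance_summary))
      as.data.frame(importance_summary),
    spearman = spearman,
    first_split_scores = first_scores,
    n_splits = n_splits,
    single_split = n_splits == 1L,
    seed = seed
  ), class = "experiment_result")
}

.run_one_split <- function(X, y, source, systems, families, need_logistic,
                           grids, spec, thresholds, pass_mat,
                           importance_repeats, split_seed, keep_scores) {
  set.seed(split_seed)
  sp <- multisource_split(source, spec)
  train <- sp$train
  std <- do.call(standardise,
                 c(list(X[train, , drop = FALSE]),
                   lapply(sp$test, function(ix) X[ix, , drop = FALSE])))
  Xtr <- std$train
  y_tr <- y[train]
  src_tr <- source[train]
  test_ix_all <- unlist(sp$test, use.names = FALSE)

  metric_rows <- list()
  importance_rows <- list()
  score_rows <- list()
  lc_importance <- NULL

  add_metrics <- function(system, cohort, scores, labels) {
    rep <- metric_report(scores, labels)
    metric_rows[[length(metric_rows) + 1L]] <<- data.table::data.table(
      cohort = cohort, system = system, metric = names(unclass(rep)),
      value = unlist(unclass(rep), use.names = FALSE))
  }
  add_scores <- function(system, cohort, scores, labels) {
    if (!keep_scores) return()
    score_rows[[length(score_rows) + 1L]] <<- data.table::data.table(
      cohort = cohort, system = system, score = scores, label = labels)
  }

  fit_family <- function(family) {
    tuned <- tune_multisource_cv(Xtr, y_tr, src_tr, family, grids[[family]])
    model <- fit_final(Xtr, y_tr, family, tuned$params)
    for (cohort in names(sp$test)) {
      Z <- std[[cohort]]
      sc <- predict_prob(model, Z)
      add_metrics(family, cohort, sc, y[sp$test[[cohort]]])
      add_scores(family, cohort, sc, y[sp$test[[cohort]]])
    }
    Z_all <- do.call(rbind, lapply(names(sp$test), function(cohort)
      std[[cohort]]))
    imp <- permutation_importance(model, Z_all, y[test_ix_all],
                                  n_repeats = importance_repeats)
    importance_rows[[length(importance_rows) + 1L]] <<- data.table::data.table(
      family = family, feature = names(imp), importance = as.numeric(imp))
    list(model = model, importance = imp)
  }

  fits <- list()
  run_families <- union(families, if (need_logistic) "logistic")
  for (family in run_families) fits[[family]] <- fit_family(family)
  if (!"logistic" %in% families && !is.null(fits$logistic)) {
    # logistic was run only to supply weights; drop its reported rows
    metric_rows <- Filter(function(d) d$system[1] != "logistic", metric_rows)
    importance_rows <- Filter(function(d) d$family[1] != "logistic",
                              importance_rows)
    score_rows <- Filter(function(d) d$system[1] != "logistic", score_rows)
  }
  if (!is.null(fits$logistic)) lc_importance <- fits$logistic$importance

  if ("nld" %in% systems || "nld_weighted" %in% systems) {
    w <- if ("nld_weighted" %in% systems) {
      weights_from_importance(lc_importance[.base_features])
    }
    for (cohort in names(sp$test)) {
      ix <- sp$test[[cohort]]
      pm <- pass_mat[ix, , drop = FALSE]
      if ("nld" %in% systems) {
        sc <- rowSums(pm) / 15
        add_metrics("nld", cohort, sc, y[ix])
        add_scores("nld", cohort, sc, y[ix])
      }
      if ("nld_weighted" %in% systems) {
        sc <- as.numeric(pm %*% w[.test_ids])
        add_metrics("nld_weighted", cohort, sc, y[ix])
        add_scores("nld_weighted", cohort, sc, y[ix])
      }
    }
  }

  list(
    metrics = data.table::rbindlist(metric_rows),
    importance = if (length(importance_rows))
      data.table::rbindlist(importance_rows),
    scores = if (keep_scores) data.table::rbindlist(score_rows)
  )
}

#' @export
print.experiment_result <- function(x, ...) {
  cat(sprintf("<experiment_result> %d split(s), %d system(s)\n",
              x$n_splits, length(unique(x$summary$system))))
  if (x$single_split) cat("  note: SDs reported as 0 (single split)\n")
  if (!is.null(x$spearman)) {
    cat(sprintf("  importance rank agreement (Spearman): %.3f\n", x$spearman))
  }
  invisible(x)
}
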