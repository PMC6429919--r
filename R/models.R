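#' Fit a probability classifier
#'
#' Two families are supported, mirroring the study design:
#' `"logistic"` — an L2-regularised logistic classifier (ridge penalty via
#' \pkg{glmnet}; `params$lambda` is the penalty strength, larger = simpler
#' model); and `"forest"` — a bagged CART random forest with per-node
#' feature subsampling, implemented natively in C++ (`params$ntree`,
#' `params$mtry`, `params$max_depth`, `params$min_leaf`). Both expose a
#' probability-of-positive score via [predict_prob()].
#'
#' Features are expected to be standardised upstream; the logistic fit does
#' not rescale internally.
#'
#' @param X Numeric feature matrix (instances x features).
#' @param y Binary labels (1 = positive/RFD).
#' @param family `"logistic"` or `"forest"`.
#' @param params Named list of hyperparameters (see above); missing entries
#'   take defaults.
#' @return Object of class `rfd_model`.
#' @export
fit_classifier <- function(X, y, family = c("logistic", "forest"),
                           params = list()) {
  family <- match.arg(family)
  y <- .as_binary(y)
  if (length(unique(y)) < 2) stop("single-class training data")
  stopifnot(is.matrix(X), nrow(X) == length(y))
  fit <- if (family == "logistic") {
    lambda <- params$lambda %||% 1e-3
    # descending path ending at the requested penalty keeps glmnet stable
    path <- sort(unique(lambda * c(100, 20, 5, 1)), decreasing = TRUE)
    list(glmnet = glmnet::glmnet(X, y, family = "binomial", alpha = 0,
                                 lambda = path, standardize = FALSE),
         lambda = lambda)
  } else {
    p <- ncol(X)
    ntree <- params$ntree %||% 100L
    mtry <- params$mtry %||% max(1L, floor(sqrt(p)))
    max_depth <- params$max_depth %||% 12L
    min_leaf <- params$min_leaf %||% 5L
    .forest_fit(X, as.integer(y), as.integer(ntree), as.integer(mtry),
                as.integer(max_depth), as.integer(min_leaf))
  }
  structure(list(family = family, fit = fit, params = params,
                 features = colnames(X)),
            class = "rfd_model")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Predict positive-class probabilities
#'
#' @param model An `rfd_model` from [fit_classifier()].
#' @param X Feature matrix on the same scale/columns as the training data.
#' @return Numeric vector of probabilities in `[0, 1]`.
#' @export
predict_prob <- function(model, X) {
  stopifnot(inherits(model, "rfd_model"))
  if (model$family == "logistic") {
    as.numeric(predict(model$fit$glmnet, newx = X, s = model$fit$lambda,
                       type = "response"))
  } else {
    .forest_predict(model$fit, X)
  }
}

#' Fitted logistic coefficients
#'
#' @param object An `rfd_model` with `family = "logistic"`.
#' @param ... Unused.
#' @return Named numeric vector of feature coefficients (intercept
#'   excluded), on the standardised-feature scale.
#' @export
coef.rfd_model <- function(object, ...) {
  if (object$family != "logistic") {
    stop("coefficients are only defined for the logistic family")
  }
  b <- as.matrix(predict(object$fit$glmnet, s = object$fit$lambda,
                         type = "coefficients"))
  setNames(b[-1, 1], rownames(b)[-1])
}

#' @export
print.rfd_model <- function(x, ...) {
  cat(sprintf("<rfd_model> family '%s', %d feature(s)\n",
              x$family, length(x$features)))
  invisible(x)
}
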