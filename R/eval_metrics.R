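#' ROC curve by threshold sweep
#'
#' Sweeps the decision threshold over the distinct score values (tied scores
#' are grouped at a single threshold), returning the operating points from
#' (0, 0) to (1, 1). The area under the trapezoidal interpolation of this
#' curve equals the concordant-pair (Mann-Whitney) probability with ties
#' counted half.
#'
#' @param scores Numeric scores, larger = more positive.
#' @param labels Binary labels (0/1, logical, or a factor whose second level
#'   is positive).
#' @return data.frame of class `roc_curve` with columns `fpr`, `tpr`,
#'   `threshold` (threshold is `Inf` at the (0,0) point).
#' @export
#' @examples
#' roc <- roc_curve(c(0.9, 0.6, 0.8, 0.4), c(1, 0, 1, 0))
#' auroc(roc)
roc_curve <- function(scores, labels) {
  y <- .as_binary(labels)
  if (length(unique(y)) < 2) stop("both classes must be present")
  stopifnot(length(scores) == length(y))
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; y <- y[o]
  grp <- c(TRUE, diff(s) != 0)          # first index of each tied group
  tp <- cumsum(y); fp <- cumsum(1 - y)
  last <- c(which(grp[-1]) , length(s)) # last index of each tied group
  P <- sum(y); N <- length(y) - P
  out <- data.frame(
    fpr = c(0, fp[last] / N),
    tpr = c(0, tp[last] / P),
    threshold = c(Inf, s[grp])
  )
  class(out) <- c("roc_curve", "data.frame")
  out
}

#' Precision-recall curve
#'
#' Same threshold sweep as [roc_curve()]; precision at recall 0 is anchored
#' at the precision of the highest-score group.
#'
#' @inheritParams roc_curve
#' @return data.frame with columns `recall`, `precision`, `threshold`.
#' @export
prc_curve <- function(scores, labels) {
  y <- .as_binary(labels)
  if (length(unique(y)) < 2) stop("both classes must be present")
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; y <- y[o]
  grp <- c(TRUE, diff(s) != 0)
  tp <- cumsum(y); fp <- cumsum(1 - y)
  last <- c(which(grp[-1]), length(s))
  P <- sum(y)
  prec <- tp[last] / (tp[last] + fp[last])
  data.frame(
    recall = c(0, tp[last] / P),
    precision = c(prec[1], prec),
    threshold = c(Inf, s[grp])
  )
}

.as_binary <- function(labels) {
  if (is.factor(labels)) labels <- as.integer(labels) - 1L
  if (is.character(labels)) labels <- as.integer(labels == "RFD")
  y <- as.numeric(labels)
  if (!all(y %in% c(0, 1))) stop("labels must be binary")
  y
}

#' Area under the ROC curve
#'
#' @param x A `roc_curve`, or raw scores (then `labels` is required).
#' @param labels Optional labels when `x` is a score vector.
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(x, labels = NULL) {
  roc <- if (inherits(x, "roc_curve")) x else roc_curve(x, labels)
  sum(diff(roc$fpr) * (head(roc$tpr, -1) + tail(roc$tpr, -1)) / 2)
}

#' Partial AUROC over the high-specificity region
#'
#' Trapezoidal area under the ROC curve restricted to
#' `fpr` in `[0, max_fpr]`, linearly interpolating the curve at the
#' boundary. A perfect classifier scores `max_fpr`; the chance diagonal
#' scores `max_fpr^2 / 2`; `max_fpr = 1` recovers the full AUROC.
#'
#' @param roc A `roc_curve`.
#' @param max_fpr Upper false-positive-rate limit, in `(0, 1]`.
#' @return Area in `[0, max_fpr]`.
#' @export
pauroc <- function(roc, max_fpr = 0.3) {
  if (!is.numeric(max_fpr) || max_fpr <= 0 || max_fpr > 1) {
    stop("max_fpr must lie in (0, 1]")
  }
  fpr <- roc$fpr; tpr <- roc$tpr
  keep <- fpr <= max_fpr
  f <- fpr[keep]; t <- tpr[keep]
  if (max(f) < max_fpr) {
    # interpolate the curve at the boundary
    i <- which(fpr > max_fpr)[1]
    w <- (max_fpr - fpr[i - 1]) / (fpr[i] - fpr[i - 1])
    f <- c(f, max_fpr)
    t <- c(t, tpr[i - 1] + w * (tpr[i] - tpr[i - 1]))
  }
  sum(diff(f) * (head(t, -1) + tail(t, -1)) / 2)
}

#' Interpolated operating point at a fixed specificity
#'
#' Locates `fpr* = 1 - specificity` on the ROC curve and linearly
#' interpolates the sensitivity between the two adjacent operating points
#' (exact on-grid points are returned unchanged). The interpolation weight
#' is also returned so downstream confusion-matrix quantities can be formed
#' as the same convex mixture of the two realised thresholds.
#'
#' @param roc A `roc_curve`.
#' @param specificity Target specificity (default 0.7).
#' @return List with `sensitivity`, `specificity` (the requested value,
#'   exactly), `fpr`, and `thresholds`/`weight` describing the mixture of
#'   the two adjacent thresholds.
#' @export
operating_point <- function(roc, specificity = 0.7) {
  target_fpr <- 1 - specificity
  fpr <- roc$fpr; tpr <- roc$tpr
  exact <- which(fpr == target_fpr)
  if (length(exact)) {
    i <- exact[length(exact)]   # on ties take the highest-tpr realisation
    return(list(sensitivity = tpr[i], specificity = specificity,
                fpr = target_fpr, thresholds = rep(roc$threshold[i], 2),
                weight = 0))
  }
  i <- which(fpr > target_fpr)[1]
  w <- (target_fpr - fpr[i - 1]) / (fpr[i] - fpr[i - 1])
  list(
    sensitivity = tpr[i - 1] + w * (tpr[i] - tpr[i - 1]),
    specificity = specificity,
    fpr = target_fpr,
    thresholds = c(roc$threshold[i - 1], roc$threshold[i]),
    weight = w
  )
}

#' Brier score
#'
#' Mean squared difference between predicted probabilities and binary
#' labels; minimised over constant predictors at the class prevalence.
#'
#' @param scores Probabilities in `[0, 1]`.
#' @param labels Binary labels.
#' @return Mean squared error in `[0, 1]`.
#' @export
brier <- function(scores, labels) {
  y <- .as_binary(labels)
  if (!length(scores)) stop("empty input")
  if (any(scores < 0 | scores > 1)) stop("scores must lie in [0, 1]")
  mean((scores - y)^2)
}

#' Spearman rank correlation with midrank ties
#'
#' @param ranking_a,ranking_b Equal-length numeric vectors over the same
#'   items (values may be ranks or raw importances; only order matters).
#' @return Correlation in `[-1, 1]`.
#' @export
spearman_rank <- function(ranking_a, ranking_b) {
  if (length(ranking_a) != length(ranking_b)) {
    stop("rankings must have equal length")
  }
  stats::cor(ranking_a, ranking_b, method = "spearman")
}

#' Full metric report for one scored test set
#'
#' The evaluation suite used throughout: AUROC, partial AUROC over
#' `fpr <= max_fpr`, Brier score, and the operating-point metrics
#' (sensitivity, specificity, accuracy, F1) at the fixed-specificity point
#' found by linear interpolation on the ROC curve. Accuracy and F1 at the
#' interpolated (virtual) threshold are computed from fractional
#' confusion-matrix entries: with prevalence p, sensitivity se and
#' specificity sp, accuracy = p se + (1 - p) sp and
#' F1 = 2 p se / (2 p se + (1 - p)(1 - sp) + p (1 - se)).
#'
#' @inheritParams roc_curve
#' @param specificity Operating-point specificity (default 0.7).
#' @param max_fpr Partial-AUROC limit (default 0.3).
#' @return Named list of class `metric_report`: `auroc`, `pauroc`,
#'   `accuracy`, `f1`, `specificity`, `sensitivity`, `brier`.
#' @export
metric_report <- function(scores, labels, specificity = 0.7, max_fpr = 0.3) {
  y <- .as_binary(labels)
  roc <- roc_curve(scores, y)
  op <- operating_point(roc, specificity)
  p <- mean(y)
  se <- op$sensitivity; sp <- specificity
  acc <- p * se + (1 - p) * sp
  f1 <- 2 * p * se / (2 * p * se + (1 - p) * (1 - sp) + p * (1 - se))
  structure(list(
    auroc = auroc(roc),
    pauroc = pauroc(roc, max_fpr),
    accuracy = acc,
    f1 = f1,
    specificity = sp,
    sensitivity = se,
    brier = brier(pmin(pmax(scores, 0), 1), y)
  ), class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat("<metric_report>\n")
  for (m in names(x)) cat(sprintf("  %-12s %.4f\n", m, x[[m]]))
  invisible(x)
}
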