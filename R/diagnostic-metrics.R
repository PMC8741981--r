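# Confusion-matrix metric battery, ROC construction and threshold selection
# for scalar diagnostic indices. Convention throughout: the positive class
# is SBT failure (label 1), and a HIGHER index value predicts failure
# (score >= threshold -> predicted positive). Thresholds are attained score
# values, never midpoints, so every reported operating point is auditable
# against the data.

#' Exact (Clopper-Pearson) binomial confidence interval
#'
#' @param x Number of successes.
#' @param n Number of trials.
#' @param conf Confidence level (default 0.95).
#' @return Numeric vector `c(lo, hi)`.
#' @export
clopper_pearson <- function(x, n, conf = 0.95) {
  if (n < 1 || x < 0 || x > n) stop("require 0 <= x <= n, n >= 1")
  a <- (1 - conf) / 2
  lo <- if (x == 0) 0 else stats::qbeta(a, x, n - x + 1)
  hi <- if (x == n) 1 else stats::qbeta(1 - a, x + 1, n - x)
  c(lo = lo, hi = hi)
}

#' Confusion counts at a threshold
#'
#' Dichotomises scores at a threshold (score >= threshold predicts the
#' positive class, i.e. SBT failure) and crosses the prediction with the
#' true labels.
#'
#' @param scores Numeric index values.
#' @param labels 0/1 labels (1 = failure, the positive class).
#' @param threshold Decision threshold.
#' @return A list of class `confusion_counts` with `tp`, `fp`, `fn`, `tn`.
#' @export
confusion_at <- function(scores, labels, threshold) {
  if (length(scores) != length(labels)) stop("scores/labels length mismatch")
  if (length(scores) < 1) stop("need at least one observation")
  if (!all(labels %in% c(0, 1))) stop("labels must be 0 or 1")
  pred <- scores >= threshold
  structure(list(
    tp = sum(pred & labels == 1),
    fp = sum(pred & labels == 0),
    fn = sum(!pred & labels == 1),
    tn = sum(!pred & labels == 0)
  ), class = "confusion_counts")
}

#' Diagnostic metric battery from a 2x2 table
#'
#' Sensitivity, specificity, predictive values and accuracy with exact
#' binomial 95% CIs, the likelihood ratios, the diagnostic odds ratio,
#' the F1 score and Matthews correlation coefficient. Degenerate
#' denominators follow the usual conventions: MCC and F1 are 0 when a
#' marginal is empty; PLR and DOR may be `Inf` (flagged by `degenerate`),
#' never an error.
#'
#' @param counts A `confusion_counts` object (or list with tp/fp/fn/tn).
#' @param conf Confidence level for the proportion CIs.
#' @return A list of class `metric_set`; proportion metrics are lists with
#'   `est`, `lo`, `hi`.
#' @export
metric_set <- function(counts, conf = 0.95) {
  tp <- counts$tp; fp <- counts$fp; fn <- counts$fn; tn <- counts$tn
  if (any(c(tp, fp, fn, tn) < 0) || tp + fp + fn + tn < 1) {
    stop("counts must be non-negative with a positive total")
  }
  prop <- function(x, n) {
    if (n == 0) return(list(est = NA_real_, lo = NA_real_, hi = NA_real_))
    ci <- clopper_pearson(x, n, conf)
    list(est = x / n, lo = unname(ci[1]), hi = unname(ci[2]))
  }
  sens <- prop(tp, tp + fn)
  spec <- prop(tn, tn + fp)
  plr <- if (!is.na(spec$est) && spec$est < 1) sens$est / (1 - spec$est) else Inf
  nlr <- if (!is.na(spec$est) && spec$est > 0) (1 - sens$est) / spec$est else Inf
  dor <- if (fp * fn > 0) (tp * tn) / (fp * fn) else if (tp * tn > 0) Inf else NA_real_
  f1 <- if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else 0
  denom <- prod(sqrt(c(tp + fp, tp + fn, tn + fp, tn + fn)))
  mcc <- if (denom > 0) (tp * tn - fp * fn) / denom else 0
  structure(list(
    counts = counts,
    sensitivity = sens,
    specificity = spec,
    ppv = prop(tp, tp + fp),
    npv = prop(tn, tn + fn),
    accuracy = prop(tp + tn, tp + fp + fn + tn),
    plr = plr, nlr = nlr, dor = dor, f1 = f1, mcc = mcc,
    degenerate = !is.finite(plr) || !is.finite(nlr) ||
      (!is.na(dor) && !is.finite(dor))
  ), class = "metric_set")
}

#' @export
print.metric_set <- function(x, ...) {
  fmt <- function(p) sprintf("%.3f (%.3f-%.3f)", p$est, p$lo, p$hi)
  cat("Diagnostic metrics (positive class = SBT failure)\n")
  cat("  sensitivity:", fmt(x$sensitivity), "\n")
  cat("  specificity:", fmt(x$specificity), "\n")
  cat("  PPV:        ", fmt(x$ppv), "\n")
  cat("  NPV:        ", fmt(x$npv), "\n")
  cat("  accuracy:   ", fmt(x$accuracy), "\n")
  cat(sprintf("  PLR %.2f  NLR %.2f  DOR %.1f  F1 %.3f  MCC %.3f\n",
              x$plr, x$nlr, x$dor, x$f1, x$mcc))
  invisible(x)
}

#' ROC curve with AUROC and DeLong inference
#'
#' Builds the ROC curve of an index against a binary outcome using attained
#' score values as thresholds. The AUROC is the Mann-Whitney probability
#' that a randomly chosen positive outscores a randomly chosen negative
#' (ties count one half); its standard error and confidence interval use
#' DeLong's structural-components estimator, and the p-value tests
#' AUROC = 0.5 (two-sided, normal approximation).
#'
#' @param scores Numeric index values (higher predicts failure).
#' @param labels 0/1 outcome labels (1 = failure).
#' @param conf Confidence level for the AUROC CI.
#' @return A list of class `roc_curve` with the (fpr, tpr) points, the
#'   threshold attaining each point, `auroc`, `auroc_ci`, `se` and `p_value`.
#' @export
roc_curve <- function(scores, labels, conf = 0.95) {
  if (length(scores) != length(labels)) stop("scores/labels length mismatch")
  if (!all(labels %in% c(0, 1))) stop("labels must be 0 or 1")
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  m <- length(pos); n <- length(neg)
  if (m == 0 || n == 0) stop("both outcome classes must be present")

  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tpr <- vapply(thr, function(t) mean(pos >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(neg >= t), numeric(1))

  # DeLong structural components: psi(X_i, Y_j) averaged over the other class
  psi <- function(x, y) (x > y) + 0.5 * (x == y)
  v10 <- vapply(pos, function(x) mean(psi(x, neg)), numeric(1))
  v01 <- vapply(neg, function(y) mean(psi(pos, y)), numeric(1))
  auc <- mean(v10)
  var_auc <- (if (m > 1) stats::var(v10) / m else 0) +
    (if (n > 1) stats::var(v01) / n else 0)
  se <- sqrt(var_auc)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  ci <- c(max(0, auc - z * se), min(1, auc + z * se))
  p <- if (se > 0) 2 * stats::pnorm(-abs((auc - 0.5) / se)) else
    as.numeric(auc == 0.5)
  structure(list(
    thresholds = thr, fpr = fpr, tpr = tpr,
    auroc = auc, se = se, auroc_ci = ci, p_value = p,
    n_pos = m, n_neg = n
  ), class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("ROC: %d positives / %d negatives\n", x$n_pos, x$n_neg))
  cat(sprintf("AUROC %.3f, 95%%CI [%.3f-%.3f], p = %.3g (vs 0.5, DeLong)\n",
              x$auroc, x$auroc_ci[1], x$auroc_ci[2], x$p_value))
  invisible(x)
}

#' Youden-optimal threshold of a ROC curve
#'
#' Returns the attained score value maximising Youden's J
#' (sensitivity + specificity - 1); ties are broken toward higher
#' specificity, i.e. the higher threshold.
#'
#' @param curve A `roc_curve` object.
#' @return The selected threshold (a finite attained score value).
#' @export
optimal_threshold <- function(curve) {
  stopifnot(inherits(curve, "roc_curve"))
  finite <- is.finite(curve$thresholds)
  # integer-scaled J (tp * n_neg - fp * n_pos) so exact rational ties are
  # recognised as ties rather than broken by floating-point noise
  j <- round(curve$tpr * curve$n_pos) * curve$n_neg -
    round(curve$fpr * curve$n_neg) * curve$n_pos
  j[!finite] <- -Inf
  best <- which(j == max(j))
  # among maximal-J points, the largest threshold gives the highest specificity
  curve$thresholds[best[which.max(curve$thresholds[best])]]
}

#' Export a ROC curve as a data frame
#'
#' @param x A `roc_curve` object.
#' @param ... Unused.
#' @return Data frame with columns `threshold`, `fpr`, `tpr`.
#' @export
as.data.frame.roc_curve <- function(x, ...) {
  data.frame(threshold = x$thresholds, fpr = x$fpr, tpr = x$tpr)
}
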