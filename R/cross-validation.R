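# Stratified, repeated k-fold cross-validation with training-fold threshold
# learning. The protocol is "prospective" in the structural sense: the
# operating threshold for each fold is learned on the training patients
# only (Youden-optimal point of the training ROC) and then applied,
# unchanged, to the held-out patients.

#' Stratified fold assignment
#'
#' Assigns each observation to one of `k` folds so that fold sizes differ
#' by at most one both overall and within each outcome class. Within a
#' class, membership is random; remainders go to the currently smallest
#' folds so the overall balance also holds.
#'
#' @param labels Vector of class labels (any type; compared with `==`).
#' @param k Number of folds (>= 2).
#' @param seed Integer seed; assignment is reproducible.
#' @return Integer vector of fold ids in 1..k, same length as `labels`.
#' @export
stratified_partition <- function(labels, k = 2, seed = 1L) {
  n <- length(labels)
  if (k < 2) stop("k must be at least 2")
  classes <- unique(labels)
  counts <- vapply(classes, function(cl) sum(labels == cl), integer(1))
  if (any(counts < k)) {
    stop("every class must have at least k members (smallest has ",
         min(counts), ")")
  }
  old <- globalenv()$.Random.seed
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  fold <- integer(n)
  load <- integer(k)
  for (cl in classes) {
    idx <- sample(which(labels == cl))
    n_cl <- length(idx)
    base <- n_cl %/% k
    rem <- n_cl %% k
    sizes <- rep(base, k)
    if (rem > 0) {
      # give the remainder to the folds currently lightest (ties: lower id)
      lightest <- order(load, seq_len(k))[seq_len(rem)]
      sizes[lightest] <- sizes[lightest] + 1
    }
    fold[idx] <- rep(seq_len(k), times = sizes)
    load <- load + sizes
  }
  fold
}

#' Cross-validated diagnostic evaluation of one index
#'
#' Runs a stratified, `repeats`-times repeated, `k`-fold cross-validation
#' of a scalar index against the SBT outcome. In each repeat the cohort is
#' re-partitioned; for every fold the Youden-optimal threshold is learned
#' on the training portion's ROC curve and the held-out portion is scored
#' at that fixed threshold, yielding a full diagnostic metric battery per
#' fold. The summary reports the unweighted arithmetic mean of each metric
#' (and of the threshold) across the k x repeats test folds; confidence
#' limits of proportion metrics are averaged fold-level Clopper-Pearson
#' bounds. Test folds that end up with a single outcome class are excluded
#' with a warning.
#'
#' @param scores Numeric index values, one per patient (higher = failure).
#' @param labels 0/1 outcome labels (1 = failure).
#' @param k Number of folds (default 2).
#' @param repeats Number of repeats (default 2).
#' @param seed Integer seed driving all partitions.
#' @return A list of class `cv_result` with a per-fold data frame `folds`,
#'   the `mean_threshold`, and `summary` (mean est/lo/hi per metric).
#' @export
run_cv <- function(scores, labels, k = 2, repeats = 2, seed = 1L) {
  if (length(scores) != length(labels)) stop("scores/labels length mismatch")
  if (!all(labels %in% c(0, 1))) stop("labels must be 0 or 1")
  if (length(unique(labels)) < 2) stop("both outcomes must be present")
  if (any(!is.finite(scores))) stop("index not computable for all patients")
  fold_rows <- list()
  for (r in seq_len(repeats)) {
    fold <- stratified_partition(labels, k, seed = seed + 7919L * (r - 1L))
    for (f in seq_len(k)) {
      test <- fold == f
      train_roc <- roc_curve(scores[!test], labels[!test])
      thr <- optimal_threshold(train_roc)
      if (length(unique(labels[test])) < 2) {
        warning(sprintf("repeat %d fold %d: single-class test fold excluded",
                        r, f))
        next
      }
      ms <- metric_set(confusion_at(scores[test], labels[test], thr))
      fold_rows[[length(fold_rows) + 1]] <- data.frame(
        repeat_ = r, fold = f, threshold = thr,
        sens = ms$sensitivity$est, sens_lo = ms$sensitivity$lo,
        sens_hi = ms$sensitivity$hi,
        spec = ms$specificity$est, spec_lo = ms$specificity$lo,
        spec_hi = ms$specificity$hi,
        ppv = ms$ppv$est, ppv_lo = ms$ppv$lo, ppv_hi = ms$ppv$hi,
        npv = ms$npv$est, npv_lo = ms$npv$lo, npv_hi = ms$npv$hi,
        accuracy = ms$accuracy$est, accuracy_lo = ms$accuracy$lo,
        accuracy_hi = ms$accuracy$hi,
        plr = ms$plr, nlr = ms$nlr, dor = ms$dor,
        f1 = ms$f1, mcc = ms$mcc
      )
    }
  }
  folds <- do.call(rbind, fold_rows)
  if (is.null(folds) || nrow(folds) == 0) stop("no usable test folds")
  metric_cols <- setdiff(names(folds), c("repeat_", "fold"))
  summary <- vapply(folds[metric_cols], function(v) mean(v[is.finite(v)]),
                    numeric(1))
  structure(list(
    folds = folds,
    k = k, repeats = repeats, seed = seed,
    mean_threshold = summary[["threshold"]],
    summary = as.list(summary)
  ), class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  s <- x$summary
  cat(sprintf("%d-times repeated %d-fold CV (%d usable folds), seed %d\n",
              x$repeats, x$k, nrow(x$folds), x$seed))
  cat(sprintf("mean threshold %.4g\n", x$mean_threshold))
  cat(sprintf(
    "mean sens %.2f (%.2f-%.2f)  spec %.2f (%.2f-%.2f)  PPV %.2f  NPV %.2f\n",
    s$sens, s$sens_lo, s$sens_hi, s$spec, s$spec_lo, s$spec_hi, s$ppv, s$npv))
  cat(sprintf("mean acc %.2f  PLR %.2f  NLR %.2f  DOR %.2f  F1 %.2f  MCC %.2f\n",
              s$accuracy, s$plr, s$nlr, s$dor, s$f1, s$mcc))
  invisible(x)
}
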