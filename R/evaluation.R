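# Metrics (sensitivity, specificity, accuracy, FPR, relative accuracy),
# rank-based ROC/AUC, and leave-one-subject-out cross-validation.
# Positive class throughout = preictal.

#' Confusion counts from predictions and truth
#'
#' @param predicted,actual vectors (logical, 0/1 or `"preictal"`-vs-other
#'   labels); the positive class is preictal.
#' @return list of class `confusion_counts` with `TP`, `TN`, `FP`, `FN`.
#' @export
confusion_counts <- function(predicted, actual) {
  to01 <- function(x) {
    if (is.character(x)) as.integer(x == "preictal") else as.integer(x)
  }
  p <- to01(predicted)
  a <- to01(actual)
  stopifnot(length(p) == length(a), all(p %in% 0:1), all(a %in% 0:1))
  structure(list(TP = sum(p == 1L & a == 1L), TN = sum(p == 0L & a == 0L),
                 FP = sum(p == 1L & a == 0L), FN = sum(p == 0L & a == 1L)),
            class = "confusion_counts")
}

#' Classification metrics from confusion counts
#'
#' Sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)`, accuracy
#' `(TP+TN)/total` and false positive rate `FP/(FP+TN)`.
#'
#' @param counts a [confusion_counts()] (or list with TP/TN/FP/FN).
#' @return list of class `metric_report`.
#' @export
confusion_metrics <- function(counts) {
  with(counts, {
    total <- TP + TN + FP + FN
    if (total == 0L) stop("empty confusion table")
    structure(
      list(sensitivity = TP / (TP + FN), specificity = TN / (TN + FP),
           accuracy = (TP + TN) / total, fpr = FP / (FP + TN),
           counts = list(TP = TP, TN = TN, FP = FP, FN = FN)),
      class = "metric_report"
    )
  })
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("<metric_report> sens %.4f | spec %.4f | acc %.4f | fpr %.4f\n",
              x$sensitivity, x$specificity, x$accuracy, x$fpr))
  invisible(x)
}

#' Relative accuracy against the majority-class baseline
#'
#' `baseline = max(class counts) / total`;
#' `relative = (accuracy / baseline - 1) * 100` percent. Relative accuracy
#' is unbounded above and may be negative.
#'
#' @param accuracy overall accuracy in \[0, 1\].
#' @param class_counts positive numeric vector of per-class sample counts.
#' @return list with `baseline` and `relative_accuracy` (percent).
#' @export
relative_accuracy <- function(accuracy, class_counts) {
  stopifnot(all(class_counts > 0), accuracy >= 0, accuracy <= 1)
  baseline <- max(class_counts) / sum(class_counts)
  list(baseline = baseline,
       relative_accuracy = (accuracy / baseline - 1) * 100)
}

#' ROC curve and AUC
#'
#' AUC via the rank (Mann-Whitney) statistic: the probability that a random
#' positive outscores a random negative, ties counted half. The curve holds
#' (FPR, TPR) at every distinct score threshold.
#'
#' @param scores numeric scores (higher = more preictal).
#' @param labels 0/1 (or preictal-vs-other) labels; both classes must be
#'   present.
#' @return list with `auc` and `curve` (data.frame `threshold`, `fpr`,
#'   `tpr`).
#' @export
roc_auc <- function(scores, labels) {
  if (is.character(labels)) labels <- as.integer(labels == "preictal")
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels), all(labels %in% 0:1))
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L) stop("both classes must be present")
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[labels == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  thresholds <- c(Inf, sort(unique(scores), decreasing = TRUE))
  curve <- t(vapply(thresholds, function(th) {
    pred <- scores >= th
    c(fpr = sum(pred & labels == 0L) / n_neg,
      tpr = sum(pred & labels == 1L) / n_pos)
  }, numeric(2)))
  list(auc = auc,
       curve = data.frame(threshold = thresholds, fpr = curve[, "fpr"],
                          tpr = curve[, "tpr"]))
}

#' Leave-one-subject-out cross-validation
#'
#' For each subject, trains on all other subjects and evaluates on the held
#' out one; the pooled report aggregates confusion counts across folds
#' (patient-independent evaluation).
#'
#' @param subjects named list of per-subject data (opaque to this
#'   function).
#' @param train_fn function(train_subjects, seed) -> fitted model.
#' @param eval_fn function(model, test_subject) -> list with `predicted`
#'   and `actual` vectors (positive class preictal).
#' @param seed integer seed, forwarded to `train_fn` per fold.
#' @return list with `per_subject` (named list of `metric_report`) and
#'   `pooled` (a `metric_report` over summed counts).
#' @export
loocv <- function(subjects, train_fn, eval_fn, seed = 42L) {
  if (length(subjects) < 2L) stop("need at least 2 subjects")
  ids <- names(subjects)
  if (is.null(ids)) ids <- paste0("subject", seq_along(subjects))
  folds <- lapply(seq_along(subjects), function(i) {
    model <- train_fn(subjects[-i], seed)
    res <- eval_fn(model, subjects[[i]])
    confusion_counts(res$predicted, res$actual)
  })
  names(folds) <- ids
  pooled <- Reduce(function(a, b) {
    list(TP = a$TP + b$TP, TN = a$TN + b$TN, FP = a$FP + b$FP,
         FN = a$FN + b$FN)
  }, folds)
  list(per_subject = lapply(folds, confusion_metrics),
       pooled = confusion_metrics(pooled),
       fold_counts = folds)
}
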