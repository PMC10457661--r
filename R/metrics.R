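# Classification metrics: AUC by the Mann-Whitney rank statistic (ties get
# half credit), and Accuracy / F1 / MCC from the 0.5-threshold confusion
# matrix.

#' Area under the ROC curve by the rank statistic
#'
#' @param score Numeric predictions.
#' @param label Binary labels (both classes required).
#' @return AUC in \[0, 1\].
#' @export
auc_rank <- function(score, label) {
  stopifnot(length(score) == length(label), all(label %in% c(0, 1)))
  n_pos <- sum(label == 1)
  n_neg <- sum(label == 0)
  if (n_pos == 0 || n_neg == 0) {
    stop("AUC undefined: need both classes", call. = FALSE)
  }
  r <- rank(score, ties.method = "average")
  (sum(r[label == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Evaluate predictions against labels
#'
#' AUC via [auc_rank()]; Accuracy, F1 and Matthews correlation coefficient
#' from the confusion matrix at threshold 0.5. MCC is 0 when any marginal of
#' the confusion matrix is empty.
#'
#' @param predictions Tibble/data frame with columns `score` and `label`
#'   (binary; both classes required).
#' @param threshold Decision threshold (default 0.5).
#' @return One-row tibble with `auc`, `accuracy`, `f1`, `mcc`, `n`.
#' @export
evaluate_predictions <- function(predictions, threshold = 0.5) {
  stopifnot(all(c("score", "label") %in% names(predictions)))
  y <- predictions$label
  if (length(unique(y)) < 2L) {
    stop("evaluation requires both classes", call. = FALSE)
  }
  s <- predictions$score
  yhat <- as.integer(s >= threshold)
  conf <- confusion_metrics(tp = sum(yhat == 1 & y == 1),
                            fp = sum(yhat == 1 & y == 0),
                            tn = sum(yhat == 0 & y == 0),
                            fn = sum(yhat == 0 & y == 1))
  tibble::tibble(auc = auc_rank(s, y), accuracy = conf$accuracy,
                 f1 = conf$f1, mcc = conf$mcc, n = length(y))
}

#' Accuracy, F1 and MCC from confusion-matrix counts
#'
#' @param tp,fp,tn,fn Confusion-matrix cell counts.
#' @return Named list `accuracy`, `f1`, `mcc`.
#' @export
confusion_metrics <- function(tp, fp, tn, fn) {
  n <- tp + fp + tn + fn
  acc <- (tp + tn) / n
  f1 <- if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  denom <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  mcc <- if (denom == 0) 0 else (tp * tn - fp * fn) / denom
  list(accuracy = acc, f1 = f1, mcc = mcc)
}
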