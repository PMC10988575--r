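# Evaluation metrics: mean absolute error for the regression tasks,
# macro/weighted F-scores for multilabel classification, and multi-seed
# summaries.

#' Mean absolute error
#'
#' `mean(|y_true - y_pred|)`; a perfect model has MAE = 0.
#'
#' @param y_true,y_pred numeric vectors of equal non-zero length.
#' @return Non-negative scalar.
#' @export
mae <- function(y_true, y_pred) {
  if (length(y_true) == 0L || length(y_true) != length(y_pred))
    stop("mae: inputs must be equal-length, non-empty vectors")
  mean(abs(y_true - y_pred))
}

#' Macro / weighted multilabel F-score
#'
#' Computes the per-class F1 from class-wise true/false positives and
#' negatives across molecules, then averages: unweighted over classes
#' (`macro`) or weighted by class support, the number of true positives-class
#' molecules per class (`weighted`). Classes with zero support contribute
#' F1 = 0 to the macro average and weight 0 to the weighted average; a class
#' with no predicted and no true positives likewise scores 0 (the common
#' zero-division convention).
#'
#' @param truth,predicted binary matrices (molecules x classes), identical
#'   shapes and class order.
#' @param average `"macro"` or `"weighted"`.
#' @return F-score in [0, 1].
#' @export
multilabel_fscore <- function(truth, predicted,
                              average = c("macro", "weighted")) {
  average <- match.arg(average)
  truth <- as.matrix(truth); predicted <- as.matrix(predicted)
  if (!identical(dim(truth), dim(predicted)))
    stop("multilabel_fscore: shape mismatch")
  if (any(!truth %in% c(0, 1)) || any(!predicted %in% c(0, 1)))
    stop("multilabel_fscore: matrices must be binary")
  tp <- colSums(truth * predicted)
  fp <- colSums((1 - truth) * predicted)
  fn <- colSums(truth * (1 - predicted))
  f1 <- ifelse(2 * tp + fp + fn > 0, 2 * tp / (2 * tp + fp + fn), 0)
  support <- colSums(truth)
  if (average == "macro") mean(f1)
  else if (sum(support) == 0) 0
  else sum(f1 * support) / sum(support)
}

#' Convert class probabilities to a binary label matrix
#'
#' @param probs matrix of per-class probabilities.
#' @param threshold decision threshold (default 0.5, config-exposed).
#' @return Binary matrix of the same shape.
#' @export
threshold_probabilities <- function(probs, threshold = 0.5) {
  (as.matrix(probs) >= threshold) + 0
}

#' Mean and standard error over repeated runs
#'
#' Multi-seed reporting: mean and standard error (sample sd / sqrt(n)) of a
#' set of scores from independent initializations.
#'
#' @param scores numeric vector, length >= 2.
#' @return Named numeric vector `c(mean, se)`.
#' @export
summarize_runs <- function(scores) {
  if (length(scores) < 2L)
    stop("summarize_runs needs at least 2 scores")
  c(mean = mean(scores), se = stats::sd(scores) / sqrt(length(scores)))
}
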