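#' Area under the ROC curve
#'
#' Computed by sweeping a threshold over the scores (tied scores move
#' together), tracing the true-positive rate TP/(TP+FN) against the
#' false-positive rate FP/(FP+TN), and integrating with the trapezoid rule.
#' Equals the probability that a random positive outscores a random negative
#' (ties counted 1/2), so it is invariant under strictly monotone transforms
#' of the scores.
#'
#' @param y_true 0/1 labels.
#' @param y_score Real-valued scores, higher = more positive.
#' @return AUC-ROC in `[0, 1]`.
#' @export
auc_roc <- function(y_true, y_score) {
  .check_binary(y_true, y_score)
  ord <- order(y_score, decreasing = TRUE)
  y <- y_true[ord]
  s <- y_score[ord]
  # threshold steps at distinct score values
  dup <- rev(duplicated(rev(s)))
  tp <- cumsum(y)[!dup]
  fp <- cumsum(1 - y)[!dup]
  tpr <- c(0, tp / sum(y_true))
  fpr <- c(0, fp / sum(1 - y_true))
  sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
}

#' Area under the precision-recall curve
#'
#' Precision TP/(TP+FP) against recall TP/(TP+FN) over the same threshold
#' sweep, integrated as the recall-weighted sum of precision (average
#' precision). A random scorer's expected PR-AUC equals the positive
#' prevalence.
#'
#' @inheritParams auc_roc
#' @return PR-AUC in `[0, 1]`.
#' @export
pr_auc <- function(y_true, y_score) {
  .check_binary(y_true, y_score)
  ord <- order(y_score, decreasing = TRUE)
  y <- y_true[ord]
  s <- y_score[ord]
  dup <- rev(duplicated(rev(s)))
  tp <- cumsum(y)[!dup]
  n_pred <- seq_along(y)[!dup]
  precision <- tp / n_pred
  recall <- tp / sum(y_true)
  sum(diff(c(0, recall)) * precision)
}

.check_binary <- function(y_true, y_score) {
  if (length(y_true) != length(y_score)) abort("`y_true` and `y_score` lengths differ.")
  if (!all(y_true %in% c(0, 1))) abort("`y_true` must be binary 0/1.")
  if (sum(y_true) == 0 || sum(y_true) == length(y_true)) {
    abort("AUC is undefined when `y_true` contains a single class.")
  }
  invisible(TRUE)
}

#' Evaluate a classifier / regressor
#'
#' `evaluate_classifier()` reports AUC-ROC and PR-AUC; `evaluate_regressor()`
#' reports Spearman and Pearson correlations and mean squared error.
#'
#' @param y_true Observed labels (binary) or responses (numeric).
#' @param y_score,y_pred Predicted scores / values.
#' @return A tibble with columns `metric`, `estimate`, `n`.
#' @export
evaluate_classifier <- function(y_true, y_score) {
  tibble(
    metric = c("auc_roc", "pr_auc"),
    estimate = c(auc_roc(y_true, y_score), pr_auc(y_true, y_score)),
    n = length(y_true)
  )
}

#' @rdname evaluate_classifier
#' @export
evaluate_regressor <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) abort("`y_true` and `y_pred` lengths differ.")
  tibble(
    metric = c("spearman", "pearson", "mse"),
    estimate = c(cor(y_true, y_pred, method = "spearman"),
                 cor(y_true, y_pred, method = "pearson"),
                 mean((y_true - y_pred)^2)),
    n = length(y_true)
  )
}
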