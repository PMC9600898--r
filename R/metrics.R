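#' Classification metrics for the four GOLD stages
#'
#' Computes accuracy, macro-averaged precision/recall/F1 and macro
#' one-vs-rest ROC AUC from predicted stages and class probabilities.
#' Per-class precision (recall) is defined as 0 when the class is never
#' predicted (never occurs). A class absent from `y_true` has undefined AUC:
#' it is reported as `NA` and excluded from the macro mean with a warning.
#'
#' Per-class ROC AUC is computed by \pkg{pROC} with a fixed direction
#' (higher probability means the class), so poor classifiers are not
#' silently flipped.
#'
#' @param y_true integer stages 0..3.
#' @param y_pred predicted stages 0..3.
#' @param probs n x 4 matrix of class probabilities (rows sum to 1),
#'   column c+1 for stage c.
#' @return object of class `metrics_report`: `accuracy`, `precision_macro`,
#'   `recall_macro`, `f1_macro`, `auc_macro_ovr`, `per_class` (data.frame)
#'   and `confusion` (4 x 4 count matrix, true stages in rows).
#' @export
compute_metrics <- function(y_true, y_pred, probs) {
  stopifnot(length(y_true) == length(y_pred), nrow(probs) == length(y_true))
  classes <- 0:3
  tf <- factor(y_true, levels = classes)
  pf <- factor(y_pred, levels = classes)
  confusion <- table(true = tf, pred = pf)
  acc <- sum(diag(confusion)) / sum(confusion)
  prec <- rec <- f1 <- auc <- rep(NA_real_, 4)
  present <- classes %in% y_true
  for (i in seq_along(classes)) {
    tp <- confusion[i, i]
    fp <- sum(confusion[, i]) - tp
    fn <- sum(confusion[i, ]) - tp
    prec[i] <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec[i] <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1[i] <- if (prec[i] + rec[i] > 0) 2 * prec[i] * rec[i] / (prec[i] + rec[i]) else 0
    if (present[i]) {
      resp <- as.integer(y_true == classes[i])
      auc[i] <- as.numeric(pROC::auc(
        pROC::roc(resp, probs[, i], levels = c(0, 1), direction = "<",
                  quiet = TRUE)))
    }
  }
  if (any(!present)) {
    warning(sprintf("classes absent from y_true (%s): AUC undefined, excluded from macro mean",
                    paste(classes[!present], collapse = ", ")))
  }
  per_class <- data.frame(class = classes, precision = prec, recall = rec,
                          f1 = f1, auc = auc)
  use <- which(present)
  structure(list(
    accuracy = acc,
    precision_macro = mean(prec[use]),
    recall_macro = mean(rec[use]),
    f1_macro = mean(f1[use]),
    auc_macro_ovr = mean(auc[use]),
    per_class = per_class,
    confusion = confusion
  ), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("accuracy %.3f | precision %.3f | recall %.3f | F1 %.3f | AUC %.3f\n",
              x$accuracy, x$precision_macro, x$recall_macro, x$f1_macro,
              x$auc_macro_ovr))
  invisible(x)
}

#' Stratified k-fold cross-validation with best-AUC model selection
#'
#' Trains one model per fold on the remaining folds, evaluates it on the
#' held-out fold, and returns the fold model with the highest validation
#' macro one-vs-rest AUC (the model-selection rule used throughout the
#' experiments).
#'
#' @param x feature matrix (samples x features).
#' @param y integer stages 0..3.
#' @param factory function `(x, y) -> model`, where the model is a list
#'   with a `predict` element: function `(x) -> n x 4 probability matrix`.
#' @param n_folds number of folds (default 5).
#' @param seed controls the stratified fold assignment.
#' @return list with `fold_metrics` (one `metrics_report` per fold),
#'   `fold_auc` (numeric), `best_fold`, `best_model`.
#' @export
cross_validate <- function(x, y, factory, n_folds = 5L, seed = 1L) {
  fold <- stratified_folds(y, n_folds, seed = seed)
  fold_metrics <- vector("list", n_folds)
  models <- vector("list", n_folds)
  for (f in seq_len(n_folds)) {
    tr <- fold != f
    model <- factory(x[tr, , drop = FALSE], y[tr])
    probs <- model$predict(x[!tr, , drop = FALSE])
    pred <- max.col(probs, ties.method = "first") - 1L
    fold_metrics[[f]] <- compute_metrics(y[!tr], pred, probs)
    models[[f]] <- model
  }
  fold_auc <- vapply(fold_metrics, function(m) m$auc_macro_ovr, numeric(1))
  best <- which.max(fold_auc)
  list(fold_metrics = fold_metrics, fold_auc = fold_auc,
       best_fold = best, best_model = models[[best]])
}
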