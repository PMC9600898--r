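# The six reference classifiers: thin adapters over established
# implementations configured with the reference hyperparameters (SVM with
# RBF kernel and probability outputs; random forest with 200 trees;
# multinomial logistic regression; gradient boosting with 100 depth-3 trees
# at learning rate 0.1; linear discriminant analysis). The two-hidden-layer
# MLP (400, 100) with L2 penalty 0.01 is fitted by the package's own dense
# network trainer, since no installed R package provides a multi-hidden-layer
# softmax MLP.

.stage_levels <- as.character(0:3)

# Expand a probability matrix over a subset of levels to all 4 stages.
.prob_full <- function(p, level_names) {
  p <- as.matrix(p)
  out <- matrix(0, nrow(p), 4, dimnames = list(NULL, .stage_levels))
  out[, level_names] <- p
  out / pmax(rowSums(out), .Machine$double.eps)
}

.relu <- function(x) x * (x > 0)

# Two-hidden-layer softmax MLP trained with full-batch Adam and L2 penalty
# alpha on the weights (not the biases).
.mlp_train <- function(x, y, hidden = c(400L, 100L), alpha = 0.01, lr = 1e-3,
                       epochs = 400L, seed = 0L) {
  set.seed(seed)
  n <- nrow(x)
  p <- ncol(x)
  yy <- as.integer(y) + 1L
  params <- list(
    W1 = .glorot(p, hidden[1]), b1 = numeric(hidden[1]),
    W2 = .glorot(hidden[1], hidden[2]), b2 = numeric(hidden[2]),
    W3 = .glorot(hidden[2], 4L), b3 = numeric(4L)
  )
  state <- .adam_init(params)
  for (ep in seq_len(epochs)) {
    h1p <- sweep(x %*% params$W1, 2, params$b1, "+")
    h1 <- .relu(h1p)
    h2p <- sweep(h1 %*% params$W2, 2, params$b2, "+")
    h2 <- .relu(h2p)
    logits <- sweep(h2 %*% params$W3, 2, params$b3, "+")
    pr <- .softmax_rows(logits)
    d_logits <- pr
    d_logits[cbind(seq_len(n), yy)] <- d_logits[cbind(seq_len(n), yy)] - 1
    d_logits <- d_logits / n
    g <- list(
      W3 = crossprod(h2, d_logits) + (alpha / n) * params$W3,
      b3 = colSums(d_logits)
    )
    d_h2 <- tcrossprod(d_logits, params$W3) * (h2p > 0)
    g$W2 <- crossprod(h1, d_h2) + (alpha / n) * params$W2
    g$b2 <- colSums(d_h2)
    d_h1 <- tcrossprod(d_h2, params$W2) * (h1p > 0)
    g$W1 <- crossprod(x, d_h1) + (alpha / n) * params$W1
    g$b1 <- colSums(d_h1)
    g <- g[names(params)]
    st <- .adam_step(params, g, state, lr)
    params <- st$params
    state <- st$state
  }
  params
}

.mlp_predict <- function(params, x) {
  h1 <- .relu(sweep(x %*% params$W1, 2, params$b1, "+"))
  h2 <- .relu(sweep(h1 %*% params$W2, 2, params$b2, "+"))
  p <- .softmax_rows(sweep(h2 %*% params$W3, 2, params$b3, "+"))
  colnames(p) <- .stage_levels
  p
}

#' Names of the six reference classifiers
#'
#' @return character vector: `svm`, `mlp`, `rf`, `lr`, `gb`, `lda`.
#' @export
baseline_names <- function() c("svm", "mlp", "rf", "lr", "gb", "lda")

#' Build a reference-classifier factory
#'
#' Returns a function `(x, y) -> model` suitable for [cross_validate()];
#' the model is a list whose `predict` element maps a feature matrix to an
#' n x 4 stage probability matrix.
#'
#' @param key one of [baseline_names()].
#' @param seed seed for the stochastic learners (rf, gb, mlp).
#' @export
make_baseline_factory <- function(key, seed = 1L) {
  if (!key %in% baseline_names()) {
    stop(sprintf("configuration error: unknown classifier key '%s'", key), call. = FALSE)
  }
  switch(key,
    svm = function(x, y) {
      yf <- factor(y, levels = .stage_levels)
      set.seed(seed)
      fit <- e1071::svm(x, yf, kernel = "radial", probability = TRUE)
      list(key = "svm", predict = function(newx) {
        p <- attr(stats::predict(fit, newx, probability = TRUE), "probabilities")
        .prob_full(p[, colnames(p), drop = FALSE], colnames(p))
      })
    },
    mlp = function(x, y) {
      params <- .mlp_train(x, y, seed = seed)
      list(key = "mlp", predict = function(newx) .mlp_predict(params, newx))
    },
    rf = function(x, y) {
      set.seed(seed)
      fit <- randomForest::randomForest(x, factor(y, levels = .stage_levels),
                                        ntree = 200)
      list(key = "rf", predict = function(newx) {
        p <- stats::predict(fit, newx, type = "prob")
        .prob_full(p, colnames(p))
      })
    },
    lr = function(x, y) {
      df <- data.frame(x, check.names = FALSE)
      df$.stage <- factor(y, levels = .stage_levels)
      fit <- nnet::multinom(.stage ~ ., data = df, trace = FALSE,
                            maxit = 500, MaxNWts = 100000, decay = 1e-4)
      list(key = "lr", predict = function(newx) {
        p <- stats::predict(fit, data.frame(newx, check.names = FALSE),
                            type = "probs")
        if (is.null(dim(p))) p <- matrix(p, nrow = 1, dimnames = list(NULL, names(p)))
        .prob_full(p, colnames(p))
      })
    },
    gb = function(x, y) {
      set.seed(seed)
      dtr <- xgboost::xgb.DMatrix(as.matrix(x), label = as.integer(y))
      fit <- xgboost::xgb.train(params = list(objective = "multi:softprob",
                                              num_class = 4, max_depth = 3,
                                              eta = 0.1, nthread = 1),
                                data = dtr, nrounds = 100, verbose = 0)
      list(key = "gb", predict = function(newx) {
        p <- stats::predict(fit, xgboost::xgb.DMatrix(as.matrix(newx)))
        if (!is.matrix(p)) p <- matrix(p, ncol = 4, byrow = TRUE)
        dimnames(p) <- list(NULL, .stage_levels)
        p
      })
    },
    lda = function(x, y) {
      # collinear inputs (e.g. lasso+pca unions) only cost LDA efficiency
      fit <- withCallingHandlers(
        MASS::lda(x, grouping = factor(y, levels = .stage_levels)),
        warning = function(w) {
          if (grepl("collinear", conditionMessage(w))) invokeRestart("muffleWarning")
        })
      list(key = "lda", predict = function(newx) {
        p <- stats::predict(fit, newx)$posterior
        .prob_full(p, colnames(p))
      })
    }
  )
}

#' Fit and evaluate the six reference classifiers
#'
#' Each classifier is trained under stratified `n_folds`-fold
#' cross-validation on the training split, the fold model with the best
#' validation macro AUC is kept, and that model is evaluated on the test
#' split.
#'
#' @param x_train,y_train training features (already selected/fused) and
#'   stages.
#' @param x_test,y_test held-out evaluation split.
#' @param classifiers subset of [baseline_names()].
#' @param n_folds CV folds (default 5).
#' @param seed master seed; per-classifier seeds are derived from it.
#' @return list with `results` (data.frame: classifier, accuracy, precision,
#'   recall, f1, auc) and `metrics` (named list of `metrics_report`s).
#' @export
run_baselines <- function(x_train, y_train, x_test, y_test,
                          classifiers = baseline_names(), n_folds = 5L,
                          seed = 1L) {
  bad <- setdiff(classifiers, baseline_names())
  if (length(bad) > 0L) {
    stop(sprintf("configuration error: unknown classifier key '%s'", bad[1]), call. = FALSE)
  }
  metrics <- list()
  rows <- list()
  for (i in seq_along(classifiers)) {
    key <- classifiers[i]
    cell_seed <- derive_seed(seed, i)
    factory <- make_baseline_factory(key, seed = cell_seed)
    cv <- cross_validate(x_train, y_train, factory, n_folds = n_folds,
                         seed = cell_seed)
    probs <- cv$best_model$predict(x_test)
    pred <- max.col(probs, ties.method = "first") - 1L
    m <- compute_metrics(y_test, pred, probs)
    metrics[[key]] <- m
    rows[[key]] <- data.frame(classifier = key, accuracy = m$accuracy,
                              precision = m$precision_macro,
                              recall = m$recall_macro, f1 = m$f1_macro,
                              auc = m$auc_macro_ovr,
                              stringsAsFactors = FALSE)
  }
  list(results = do.call(rbind, c(rows, list(make.row.names = FALSE))),
       metrics = metrics)
}
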