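# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: AUC by O(n^2) pair counting, metrics by direct
# confusion counting, soft-threshold closed forms for orthonormal lasso.

# Mann-Whitney pairwise AUC: (#correctly ordered pos/neg pairs + 0.5 ties) / #pairs
oracle_auc_pairwise <- function(is_pos, score) {
  p <- score[is_pos == 1]
  n <- score[is_pos == 0]
  tot <- 0
  for (a in p) for (b in n) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(p) * length(n))
}

# Brute-force 4-class metrics from direct counts.
oracle_metrics <- function(y_true, y_pred, probs) {
  classes <- 0:3
  present <- classes %in% y_true
  prec <- rec <- f1 <- numeric(4)
  auc <- rep(NA_real_, 4)
  for (c in classes) {
    i <- c + 1L
    tp <- sum(y_true == c & y_pred == c)
    fp <- sum(y_true != c & y_pred == c)
    fn <- sum(y_true == c & y_pred != c)
    prec[i] <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec[i] <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1[i] <- if (prec[i] + rec[i] > 0) 2 * prec[i] * rec[i] / (prec[i] + rec[i]) else 0
    if (present[i]) auc[i] <- oracle_auc_pairwise(as.integer(y_true == c), probs[, i])
  }
  list(accuracy = mean(y_true == y_pred),
       precision_macro = mean(prec[present]),
       recall_macro = mean(rec[present]),
       f1_macro = mean(f1[present]),
       auc_macro_ovr = mean(auc[present]))
}

# Design with columns orthonormal and orthogonal to the intercept, so the
# lasso solution is the soft threshold beta_j = S(x_j' y, n * lambda).
make_orthonormal_design <- function(n, p, seed) {
  set.seed(seed)
  q <- qr.Q(qr(cbind(1, matrix(rnorm(n * (p + 2)), n, p + 2))))[, 2:(p + 1), drop = FALSE]
  colnames(q) <- sprintf("x%d", seq_len(p))
  q
}

soft_threshold <- function(z, t) sign(z) * pmax(abs(z) - t, 0)

# Small labelled pool with named node/risk columns for episode tests.
make_pool <- function(n_per_class = 8L, d = 4L, K = 2L, seed = 1L) {
  set.seed(seed)
  n <- 4L * n_per_class
  stages <- rep(0:3, each = n_per_class)
  cols <- c(sprintf("node%d", seq_len(d)), sprintf("risk%d", seq_len(K)))
  x <- matrix(rnorm(n * (d + K)) + stages, n, d + K,
              dimnames = list(sprintf("S%03d", seq_len(n)), cols))
  list(features = x, stages = stages,
       spec = build_combination(sprintf("risk%d", seq_len(K)),
                                sprintf("node%d", seq_len(d))))
}

random_probs <- function(n, seed) {
  set.seed(seed)
  p <- matrix(stats::rexp(n * 4), n, 4)
  p / rowSums(p)
}
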