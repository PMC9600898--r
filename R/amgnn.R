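#' Auto-metric graph neural network configuration
#'
#' Hyperparameters of the episodic AMGNN classifier. Defaults follow the
#' 4-way-10-shot setting: 600 iterations, 28 episodes per optimizer step,
#' seed 42.
#'
#' @param n_way number of classes per episode (the 4 GOLD stages).
#' @param k_shot labelled support samples per class per episode.
#' @param n_query unknown query nodes per training episode.
#' @param hidden width of each graph layer's fully-connected update.
#' @param leaky_slope negative slope of LeakyReLU activations.
#' @param lr Adam learning rate.
#' @param iterations optimizer steps.
#' @param batch_size episodes per optimizer step.
#' @param tau risk-factor kernel bandwidth(s) for the edge constraint matrix
#'   (scalar or length-K, on standardized risk values).
#' @param ensemble support-graph ensemble size at prediction time.
#' @param use_constraints gate edges by the risk-factor constraint matrix E.
#' @param include_risk_in_nodes also concatenate risk factors into the node
#'   feature matrix (by default they feed E only).
#' @param seed RNG seed for initialization and episode sampling.
#' @return list of class `amgnn_config`.
#' @export
amgnn_config <- function(n_way = 4L, k_shot = 10L, n_query = 1L, hidden = 48L,
                         leaky_slope = 0.01, lr = 1e-3, iterations = 600L,
                         batch_size = 28L, tau = 1, ensemble = 5L,
                         use_constraints = TRUE, include_risk_in_nodes = FALSE,
                         seed = 42L) {
  cfg <- list(n_way = as.integer(n_way), k_shot = as.integer(k_shot),
              n_query = as.integer(n_query), hidden = as.integer(hidden),
              leaky_slope = leaky_slope, lr = lr,
              iterations = as.integer(iterations),
              batch_size = as.integer(batch_size), tau = tau,
              ensemble = as.integer(ensemble),
              use_constraints = isTRUE(use_constraints),
              include_risk_in_nodes = isTRUE(include_risk_in_nodes),
              seed = as.integer(seed))
  class(cfg) <- "amgnn_config"
  cfg
}

.lrelu <- function(x, slope) x * (x > 0) + slope * x * (x <= 0)
.dlrelu <- function(x, slope) (x > 0) + slope * (x <= 0)
.sigmoid <- function(x) stats::plogis(x)

.softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  ez <- exp(z)
  ez / rowSums(ez)
}

.glorot <- function(fan_in, fan_out) {
  matrix(stats::rnorm(fan_in * fan_out, sd = sqrt(2 / (fan_in + fan_out))),
         fan_in, fan_out)
}

.metric_hidden <- function(w) max(32L, as.integer(ceiling(w / 4)))

#' Initialize AMGNN parameters
#'
#' Two graph layers (each a pairwise metric network plus a fully-connected
#' node update) and a linear softmax head. The metric network of layer l is
#' a 1x1-kernel stack over the current channel width w_l: w_l -> max(32,
#' w_l/4) -> 1 with LeakyReLU between and a logistic squash, so edge weights
#' live in (0, 1).
#'
#' @param d node-feature dimension entering the first layer (before the
#'   label block, which adds `n_way` channels).
#' @param K number of risk factors (0 disables constraints).
#' @param config an [amgnn_config()].
#' @param seed optional seed (when `NULL`, uses the current RNG state).
#' @return nested list of parameter arrays (`m1`, `fc1`, `m2`, `fc2`,
#'   `head`).
#' @export
amgnn_init <- function(d, K, config = amgnn_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  H <- config$hidden
  c0 <- d + config$n_way
  c1 <- c0 + H
  h1 <- .metric_hidden(c0)
  h2 <- .metric_hidden(c1)
  list(
    m1 = list(W1 = .glorot(c0, h1), b1 = numeric(h1),
              w2 = as.vector(.glorot(h1, 1L)), b2 = 0),
    fc1 = list(W = .glorot(c0, H), b = numeric(H)),
    m2 = list(W1 = .glorot(c1, h2), b1 = numeric(h2),
              w2 = as.vector(.glorot(h2, 1L)), b2 = 0),
    fc2 = list(W = .glorot(c1, H), b = numeric(H)),
    head = list(W = .glorot(c1 + H, config$n_way), b = numeric(config$n_way))
  )
}

# Pairwise signed differences: row r = (j-1)*N + i holds v_i - v_j, so
# matrix(col, N, N) is indexed [i, j] (column-major). Index vectors are
# cached per N (episodes share their size within a run).
.pair_idx_cache <- new.env(parent = emptyenv())
.pair_diff <- function(v) {
  n <- nrow(v)
  key <- as.character(n)
  idx <- .pair_idx_cache[[key]]
  if (is.null(idx)) {
    idx <- list(i = rep(seq_len(n), times = n), j = rep(seq_len(n), each = n))
    .pair_idx_cache[[key]] <- idx
  }
  list(d = v[idx$i, , drop = FALSE] - v[idx$j, , drop = FALSE],
       idx_i = idx$i, idx_j = idx$j)
}

# Fast row-broadcast bias add.
.add_bias <- function(m, b) m + rep(b, each = nrow(m))

#' Learned-metric edge weight matrix
#'
#' For node representations V (N x w), forms the pairwise absolute
#' difference block |v_i - v_j| and maps its w channels through the metric
#' network theta (1x1 stack w -> h -> 1, LeakyReLU between), squashing with
#' the logistic function: W_ij = sigma(f_theta(|v_i - v_j|)). Symmetric by
#' construction; the diagonal is sigma(f_theta(0)).
#'
#' @param v numeric matrix N x w of node representations.
#' @param theta metric parameters: list `W1` (w x h), `b1`, `w2` (h), `b2`.
#' @param slope LeakyReLU negative slope.
#' @return N x N edge weight matrix with entries in (0, 1).
#' @export
edge_weight_matrix <- function(v, theta, slope = 0.01) {
  if (!all(is.finite(v))) stop("data error: non-finite node features", call. = FALSE)
  n <- nrow(v)
  pd <- .pair_diff(v)
  cabs <- abs(pd$d)
  a1 <- sweep(cabs %*% theta$W1, 2, theta$b1, "+")
  h <- .lrelu(a1, slope)
  z <- as.vector(h %*% theta$w2) + theta$b2
  matrix(.sigmoid(z), n, n)
}

#' Risk-factor edge constraint matrix
#'
#' Gaussian product kernel over the K standardized risk factors:
#' E_ij = prod_k exp(-(r_ik - r_jk)^2 / tau_k). Entries lie in (0, 1], the
#' diagonal is exactly 1, and pairs with similar risk-factor profiles keep
#' edge multipliers near 1 (the probability-constraint semantics).
#'
#' @param r numeric matrix N x K of standardized risk-factor values.
#' @param tau positive bandwidth(s), scalar or length K.
#' @return N x N symmetric constraint matrix.
#' @export
edge_constraint_matrix <- function(r, tau = 1) {
  r <- as.matrix(r)
  K <- ncol(r)
  if (any(tau <= 0)) stop("parameter error: tau must be positive", call. = FALSE)
  tau <- rep_len(tau, max(K, 1L))
  n <- nrow(r)
  s <- matrix(0, n, n)
  for (k in seq_len(K)) {
    s <- s + outer(r[, k], r[, k], "-")^2 / tau[k]
  }
  exp(-s)
}

#' Episode adjacency from edge weights and constraints
#'
#' Elementwise product M = W * E followed by row normalization, so the
#' adjacency acts as a convex-combination (weighted averaging) operator.
#'
#' @param w edge weight matrix.
#' @param e edge constraint matrix (same shape).
#' @return row-stochastic adjacency matrix.
#' @export
adjacency <- function(w, e) {
  if (!all(dim(w) == dim(e))) stop("dimension error: W and E differ in shape", call. = FALSE)
  m <- w * e
  rs <- rowSums(m)
  if (any(rs == 0)) stop("degenerate-graph error: a node has no edge mass", call. = FALSE)
  m / rs
}

#' One graph layer: aggregate, update, concatenate
#'
#' Gn(V) = LeakyReLU(A V W_f + b_f); the layer output is the concatenation
#' [V || Gn(V)], a skip connection that preserves the input representation.
#'
#' @param v node representations N x w.
#' @param a row-stochastic adjacency N x N.
#' @param layer_params list `W` (w x hidden), `b`.
#' @param slope LeakyReLU negative slope.
#' @return N x (w + hidden) matrix.
#' @export
layer_forward <- function(v, a, layer_params, slope = 0.01) {
  if (ncol(a) != nrow(v) || nrow(a) != nrow(v)) {
    stop("dimension error: adjacency and node matrix do not conform", call. = FALSE)
  }
  if (nrow(layer_params$W) != ncol(v)) {
    stop("dimension error: layer weights do not conform", call. = FALSE)
  }
  g <- .lrelu(sweep((a %*% v) %*% layer_params$W, 2, layer_params$b, "+"), slope)
  cbind(v, g)
}

.assemble_episode <- function(support_x, support_r, support_labels, support_ids,
                              query_x, query_r, query_labels, query_ids, n_way) {
  ep <- list(
    support_ids = support_ids, query_ids = query_ids,
    node_features = rbind(support_x, query_x),
    risk_values = rbind(support_r, query_r),
    support_labels = as.integer(support_labels),
    query_labels = if (is.null(query_labels)) NULL else as.integer(query_labels),
    n_way = as.integer(n_way)
  )
  class(ep) <- "amgnn_episode"
  ep
}

#' Sample an N-way K-shot episode
#'
#' Draws `k_shot` labelled support samples from each of the `n_way` stages
#' plus `n_query` query samples (from any stage, disjoint from the support)
#' out of a labelled pool, extracting node-feature and risk-factor columns
#' per the combination spec. A 4-way-10-shot episode has 40 support nodes.
#'
#' @param features standardized numeric matrix (samples x features) with
#'   rownames; must contain all combination-spec columns.
#' @param stages integer stage labels 0..3 aligned with `features`.
#' @param spec a [build_combination()] object.
#' @param n_way,k_shot,n_query episode shape.
#' @param seed optional seed; `NULL` continues the current RNG stream.
#' @param include_risk_in_nodes concatenate risk factors into node features.
#' @return object of class `amgnn_episode` with `support_ids`, `query_ids`,
#'   `node_features`, `risk_values`, `support_labels`, `query_labels`.
#' @export
sample_episode <- function(features, stages, spec, n_way = 4L, k_shot = 10L,
                           n_query = 1L, seed = NULL,
                           include_risk_in_nodes = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  node_cols <- if (include_risk_in_nodes) c(spec$risk_factors, spec$node_features) else spec$node_features
  missing_cols <- setdiff(c(node_cols, spec$risk_factors), colnames(features))
  if (length(missing_cols) > 0L) {
    stop(sprintf("episode error: features lack columns: %s",
                 paste(utils::head(missing_cols, 3), collapse = ", ")), call. = FALSE)
  }
  support <- integer(0)
  for (cl in 0:(n_way - 1L)) {
    idx <- which(stages == cl)
    if (length(idx) < k_shot) {
      stop(sprintf("episode error: class %d has %d samples, need k_shot = %d",
                   cl, length(idx), k_shot), call. = FALSE)
    }
    support <- c(support, idx[sample.int(length(idx), k_shot)])
  }
  rest <- setdiff(seq_along(stages), support)
  if (length(rest) < n_query) {
    stop("episode error: not enough samples left for the query set", call. = FALSE)
  }
  query <- rest[sample.int(length(rest), n_query)]
  .assemble_episode(
    support_x = features[support, node_cols, drop = FALSE],
    support_r = features[support, spec$risk_factors, drop = FALSE],
    support_labels = stages[support],
    support_ids = rownames(features)[support],
    query_x = features[query, node_cols, drop = FALSE],
    query_r = features[query, spec$risk_factors, drop = FALSE],
    query_labels = stages[query],
    query_ids = rownames(features)[query],
    n_way = n_way
  )
}

# Label block of the input representation: one-hot for support nodes,
# uniform 1/n_way for query nodes (their stage is unknown to the network).
.label_block <- function(episode) {
  ns <- length(episode$support_labels)
  nq <- length(episode$query_ids)
  lab <- matrix(0, ns + nq, episode$n_way)
  lab[cbind(seq_len(ns), episode$support_labels + 1L)] <- 1
  if (nq > 0L) lab[ns + seq_len(nq), ] <- 1 / episode$n_way
  lab
}

.episode_constraint <- function(episode, config) {
  n <- nrow(episode$node_features)
  if (config$use_constraints && ncol(episode$risk_values) > 0L) {
    edge_constraint_matrix(episode$risk_values, config$tau)
  } else {
    matrix(1, n, n)
  }
}

# One full graph layer with caches for backprop: learned-metric W from the
# current representation, gate by E, row-normalize, aggregate, FC + LeakyReLU,
# concatenate.
.full_layer <- function(v, e, m, fc, slope) {
  n <- nrow(v)
  pd <- .pair_diff(v)
  s <- sign(pd$d)
  cabs <- abs(pd$d)
  a1 <- .add_bias(cabs %*% m$W1, m$b1)
  # LeakyReLU is piecewise linear through the origin: value = x * local
  # slope, and the local-slope matrix doubles as the backward derivative.
  da1 <- slope + (1 - slope) * (a1 > 0)
  hm <- a1 * da1
  z <- as.vector(hm %*% m$w2) + m$b2
  wvec <- .sigmoid(z)
  wmat <- matrix(wvec, n, n)
  mm <- wmat * e
  rs <- rowSums(mm)
  atil <- mm / rs
  u <- atil %*% v
  pre <- .add_bias(u %*% fc$W, fc$b)
  dpre <- slope + (1 - slope) * (pre > 0)
  g <- pre * dpre
  list(v_out = cbind(v, g),
       cache = list(v = v, idx_i = pd$idx_i, idx_j = pd$idx_j, s = s,
                    cabs = cabs, da1 = da1, hm = hm, wvec = wvec, e = e,
                    rs = rs, atil = atil, u = u, dpre = dpre,
                    hdim = ncol(pre)))
}

.full_layer_backward <- function(cache, d_vout, m, fc, slope) {
  w <- ncol(cache$v)
  hdim <- cache$hdim
  d_v_direct <- d_vout[, seq_len(w), drop = FALSE]
  d_g <- d_vout[, w + seq_len(hdim), drop = FALSE]
  d_pre <- d_g * cache$dpre
  g_fc <- list(W = crossprod(cache$u, d_pre), b = colSums(d_pre))
  d_u <- tcrossprod(d_pre, fc$W)
  d_atil <- tcrossprod(d_u, cache$v)
  d_v_agg <- crossprod(cache$atil, d_u)
  q <- rowSums(d_atil * cache$atil)
  d_m <- (d_atil - q) / cache$rs
  d_wmat <- d_m * cache$e
  d_z <- as.vector(d_wmat) * cache$wvec * (1 - cache$wvec)
  g_m <- list(W1 = NULL, b1 = NULL,
              w2 = as.vector(crossprod(cache$hm, d_z)), b2 = sum(d_z))
  d_hm <- tcrossprod(d_z, m$w2)
  d_a1 <- d_hm * cache$da1
  g_m$W1 <- crossprod(cache$cabs, d_a1)
  g_m$b1 <- colSums(d_a1)
  d_cabs <- tcrossprod(d_a1, m$W1)
  d_d <- d_cabs * cache$s
  d_v_pair <- rowsum(d_d, cache$idx_i) - rowsum(d_d, cache$idx_j)
  list(d_v = d_v_direct + d_v_agg + d_v_pair, g_m = g_m, g_fc = g_fc)
}

#' AMGNN forward pass
#'
#' Runs an episode through two graph layers (the learned-metric adjacency is
#' recomputed from the current representation at each layer; the risk-factor
#' constraint E is computed once) and a linear softmax head on the query
#' rows.
#'
#' @param episode an [sample_episode()] object.
#' @param params parameters from [amgnn_init()] or [meta_train()].
#' @param config an [amgnn_config()].
#' @return N_q x n_way matrix of query class probabilities (rows sum to 1).
#' @export
amgnn_forward <- function(episode, params, config = amgnn_config()) {
  ns <- length(episode$support_labels)
  nq <- length(episode$query_ids)
  v0 <- cbind(episode$node_features, .label_block(episode))
  e <- .episode_constraint(episode, config)
  l1 <- .full_layer(v0, e, params$m1, params$fc1, config$leaky_slope)
  l2 <- .full_layer(l1$v_out, e, params$m2, params$fc2, config$leaky_slope)
  logits <- sweep(l2$v_out[ns + seq_len(nq), , drop = FALSE] %*% params$head$W,
                  2, params$head$b, "+")
  p <- .softmax_rows(logits)
  rownames(p) <- episode$query_ids
  p
}

.amgnn_loss_grad <- function(episode, params, config) {
  ns <- length(episode$support_labels)
  nq <- length(episode$query_ids)
  n <- ns + nq
  v0 <- cbind(episode$node_features, .label_block(episode))
  e <- .episode_constraint(episode, config)
  l1 <- .full_layer(v0, e, params$m1, params$fc1, config$leaky_slope)
  l2 <- .full_layer(l1$v_out, e, params$m2, params$fc2, config$leaky_slope)
  q_rows <- ns + seq_len(nq)
  vq <- l2$v_out[q_rows, , drop = FALSE]
  logits <- sweep(vq %*% params$head$W, 2, params$head$b, "+")
  p <- .softmax_rows(logits)
  yy <- episode$query_labels + 1L
  loss <- -mean(log(pmax(p[cbind(seq_len(nq), yy)], 1e-12)))
  d_logits <- p
  d_logits[cbind(seq_len(nq), yy)] <- d_logits[cbind(seq_len(nq), yy)] - 1
  d_logits <- d_logits / nq
  g_head <- list(W = crossprod(vq, d_logits), b = colSums(d_logits))
  d_v2 <- matrix(0, n, ncol(l2$v_out))
  d_v2[q_rows, ] <- tcrossprod(d_logits, params$head$W)
  b2 <- .full_layer_backward(l2$cache, d_v2, params$m2, params$fc2, config$leaky_slope)
  b1 <- .full_layer_backward(l1$cache, b2$d_v, params$m1, params$fc1, config$leaky_slope)
  list(loss = loss,
       grads = list(m1 = b1$g_m, fc1 = b1$g_fc, m2 = b2$g_m, fc2 = b2$g_fc,
                    head = g_head))
}

.tree_map2 <- function(f, a, b) {
  if (is.list(a)) Map(function(x, y) .tree_map2(f, x, y), a, b) else f(a, b)
}
.tree_map <- function(f, a) {
  if (is.list(a)) lapply(a, function(x) .tree_map(f, x)) else f(a)
}

.adam_init <- function(params) {
  list(m = .tree_map(function(p) p * 0, params),
       v = .tree_map(function(p) p * 0, params), t = 0L)
}

.adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- .tree_map2(function(m, g) beta1 * m + (1 - beta1) * g, state$m, grads)
  state$v <- .tree_map2(function(v, g) beta2 * v + (1 - beta2) * g^2, state$v, grads)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  upd <- .tree_map2(function(m, v) (m / bc1) / (sqrt(v / bc2) + eps), state$m, state$v)
  params <- .tree_map2(function(p, u) p - lr * u, params, upd)
  list(params = params, state = state)
}

#' Meta-train the AMGNN
#'
#' Episodic training: at every iteration a batch of independent episodes
#' (each `n_way * k_shot` support nodes plus `n_query` unknown training
#' nodes) is sampled from the training pool, the cross-entropy on the query
#' nodes is averaged over the batch, and one Adam step is taken. The full
#' run is deterministic given `config$seed`.
#'
#' @param features standardized training feature matrix (rownames = ids),
#'   containing all combination-spec columns.
#' @param stages integer stage labels aligned with `features`.
#' @param spec a [build_combination()] object.
#' @param config an [amgnn_config()].
#' @return object of class `amgnn_model`: `params`, `config`, `spec`,
#'   `loss_history` (one mean loss per iteration), `d` (node-input width).
#' @export
meta_train <- function(features, stages, spec, config = amgnn_config()) {
  if (config$use_constraints && spec$K == 0L) {
    stop("configuration error: edge constraints requested but the spec has no risk factors",
         call. = FALSE)
  }
  node_cols <- if (config$include_risk_in_nodes) {
    c(spec$risk_factors, spec$node_features)
  } else {
    spec$node_features
  }
  d <- length(node_cols)
  if (d == 0L) stop("configuration error: empty node-feature list", call. = FALSE)
  set.seed(config$seed)
  params <- amgnn_init(d, spec$K, config)
  state <- .adam_init(params)
  loss_history <- numeric(config$iterations)
  for (it in seq_len(config$iterations)) {
    grad_acc <- NULL
    loss_sum <- 0
    for (b in seq_len(config$batch_size)) {
      ep <- sample_episode(features, stages, spec, n_way = config$n_way,
                           k_shot = config$k_shot, n_query = config$n_query,
                           include_risk_in_nodes = config$include_risk_in_nodes)
      lg <- .amgnn_loss_grad(ep, params, config)
      loss_sum <- loss_sum + lg$loss
      grad_acc <- if (is.null(grad_acc)) lg$grads else .tree_map2(`+`, grad_acc, lg$grads)
    }
    grad_acc <- .tree_map(function(g) g / config$batch_size, grad_acc)
    st <- .adam_step(params, grad_acc, state, config$lr)
    params <- st$params
    state <- st$state
    loss_history[it] <- loss_sum / config$batch_size
  }
  structure(list(params = params, config = config, spec = spec,
                 node_cols = node_cols, loss_history = loss_history, d = d),
            class = "amgnn_model")
}

#' @export
print.amgnn_model <- function(x, ...) {
  cat(sprintf("amgnn_model: %d node features + %d risk factors, %d iterations\n",
              x$d, x$spec$K, x$config$iterations))
  if (x$config$iterations > 0L) {
    cat(sprintf("  final loss: %.4f\n", x$loss_history[x$config$iterations]))
  }
  invisible(x)
}

#' Classify new samples with a trained AMGNN
#'
#' Each new sample is inserted as the single unknown node into
#' `n_ensemble` independently sampled support graphs drawn from the training
#' pool; the softmax outputs are averaged and the argmax (ties broken toward
#' the lowest stage) is the predicted stage.
#'
#' @param object trained [meta_train()] model.
#' @param newdata standardized feature matrix of samples to classify (same
#'   columns/standardization as the training pool).
#' @param train_features,train_stages the labelled pool supplying support
#'   nodes.
#' @param n_ensemble support graphs per sample (default from the config).
#' @param seed RNG seed for support sampling.
#' @param ... unused.
#' @return list with `stage` (named integer vector) and `probs`
#'   (n x n_way matrix of ensemble-averaged probabilities).
#' @export
predict.amgnn_model <- function(object, newdata, train_features, train_stages,
                                n_ensemble = NULL, seed = 1L, ...) {
  config <- object$config
  spec <- object$spec
  if (is.null(n_ensemble)) n_ensemble <- config$ensemble
  set.seed(seed)
  n_new <- nrow(newdata)
  probs <- matrix(0, n_new, config$n_way)
  rownames(probs) <- rownames(newdata)
  node_cols <- object$node_cols
  for (i in seq_len(n_new)) {
    acc <- matrix(0, 1, config$n_way)
    for (r in seq_len(n_ensemble)) {
      base <- sample_episode(train_features, train_stages, spec,
                             n_way = config$n_way, k_shot = config$k_shot,
                             n_query = 0L,
                             include_risk_in_nodes = config$include_risk_in_nodes)
      ep <- .assemble_episode(
        support_x = base$node_features, support_r = base$risk_values,
        support_labels = base$support_labels, support_ids = base$support_ids,
        query_x = newdata[i, node_cols, drop = FALSE],
        query_r = newdata[i, spec$risk_factors, drop = FALSE],
        query_labels = NULL, query_ids = rownames(newdata)[i],
        n_way = config$n_way
      )
      acc <- acc + amgnn_forward(ep, object$params, config)
    }
    probs[i, ] <- acc / n_ensemble
  }
  stage <- apply(probs, 1, which.max) - 1L
  list(stage = stage, probs = probs)
}

#' Save / load an AMGNN model checkpoint
#'
#' The checkpoint is a single RDS archive (parameters + config + spec) with
#' a JSON sidecar of hyperparameters for inspection.
#'
#' @param model an `amgnn_model`.
#' @param path checkpoint path (`.rds`); the sidecar is `paste0(path, ".json")`.
#' @return `load_amgnn` returns the model.
#' @export
save_amgnn <- function(model, path) {
  saveRDS(model, path)
  side <- model$config
  class(side) <- NULL
  side$K <- model$spec$K
  side$d <- model$spec$d
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname save_amgnn
#' @export
load_amgnn <- function(path) {
  readRDS(path)
}
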