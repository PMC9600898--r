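test_that("episodes have k_shot support nodes per class, disjoint query, seeded determinism", {
  pool <- make_pool(n_per_class = 12, d = 4, K = 2, seed = 1)
  ep <- sample_episode(pool$features, pool$stages, pool$spec,
                       n_way = 4, k_shot = 10, n_query = 1, seed = 5)
  expect_length(ep$support_ids, 40)
  expect_equal(as.vector(table(factor(ep$support_labels, levels = 0:3))),
               rep(10, 4))
  expect_length(intersect(ep$support_ids, ep$query_ids), 0)
  expect_equal(nrow(ep$node_features), 41)
  expect_equal(ncol(ep$node_features), 4)
  expect_equal(ncol(ep$risk_values), 2)

  ep2 <- sample_episode(pool$features, pool$stages, pool$spec,
                        n_way = 4, k_shot = 10, n_query = 1, seed = 5)
  expect_identical(ep$support_ids, ep2$support_ids)
  expect_identical(ep$query_ids, ep2$query_ids)

  small <- make_pool(n_per_class = 5, seed = 2)
  expect_error(sample_episode(small$features, small$stages, small$spec,
                              k_shot = 10), "episode error.*class 0")
})

test_that("edge weights are symmetric, in (0,1), and match the frozen-metric Manhattan oracle", {
  set.seed(6)
  v <- matrix(rnorm(7 * 5), 7, 5)
  theta <- list(W1 = matrix(rnorm(5 * 32), 5, 32), b1 = rnorm(32),
                w2 = rnorm(32), b2 = 0.3)
  w <- edge_weight_matrix(v, theta)
  expect_equal(max(abs(w - t(w))), 0)
  expect_true(all(w > 0 & w < 1))

  # duplicate nodes: W_ij equals the diagonal value sigma(f(0))
  v2 <- v
  v2[2, ] <- v2[1, ]
  w2 <- edge_weight_matrix(v2, theta)
  expect_equal(w2[1, 2], w2[1, 1])

  # frozen channel-sum metric: W_ij = sigmoid(Manhattan distance)
  frozen <- list(W1 = matrix(1, 5, 1), b1 = 0, w2 = 1, b2 = 0)
  wf <- edge_weight_matrix(v, frozen)
  manhattan <- as.matrix(dist(v, method = "manhattan"))
  expect_equal(wf, plogis(manhattan), tolerance = 1e-12, ignore_attr = TRUE)

  v_bad <- v
  v_bad[1, 1] <- Inf
  expect_error(edge_weight_matrix(v_bad, theta), "data error")
})

test_that("edge constraints are a Gaussian product kernel with unit diagonal", {
  set.seed(7)
  r <- matrix(rnorm(6 * 3), 6, 3)
  e <- edge_constraint_matrix(r, tau = c(1, 2, 0.5))
  expect_equal(diag(e), rep(1, 6))
  expect_equal(e, t(e))
  expect_true(all(e > 0 & e <= 1))
  expect_equal(e[2, 5],
               prod(exp(-(r[2, ] - r[5, ])^2 / c(1, 2, 0.5))), tolerance = 1e-12)

  # closed form: N=2, K=1, r = (0,1), tau=1
  e2 <- edge_constraint_matrix(matrix(c(0, 1), 2, 1), tau = 1)
  expect_equal(e2[1, 2], exp(-1), tolerance = 1e-12)

  # identical rows: constraint inactive
  same <- edge_constraint_matrix(matrix(1, 4, 2), tau = 1)
  expect_equal(same, matrix(1, 4, 4))

  expect_error(edge_constraint_matrix(r, tau = 0), "parameter error")
})

test_that("adjacency is the row-normalized elementwise product", {
  set.seed(8)
  w <- matrix(runif(25, 0.1, 1), 5, 5)
  w <- (w + t(w)) / 2
  e <- matrix(runif(25, 0.1, 1), 5, 5)
  e <- (e + t(e)) / 2
  a <- adjacency(w, e)
  expect_equal(rowSums(a), rep(1, 5), tolerance = 1e-10)
  m <- w * e
  expect_equal(a, m / rowSums(m), tolerance = 1e-12)

  # constraint off: row-normalized W
  a1 <- adjacency(w, matrix(1, 5, 5))
  expect_equal(a1, w / rowSums(w), tolerance = 1e-12)

  w0 <- w
  w0[3, ] <- 0
  expect_error(adjacency(w0, e), "degenerate-graph")
  expect_error(adjacency(w, e[1:4, 1:4]), "dimension error")
})

test_that("layer_forward concatenates the LeakyReLU update", {
  set.seed(9)
  v <- matrix(rnorm(3 * 4), 3, 4)
  a <- matrix(1 / 3, 3, 3)
  lp <- list(W = matrix(rnorm(4 * 6), 4, 6), b = rnorm(6))
  out <- layer_forward(v, a, lp)
  expect_equal(dim(out), c(3, 10))
  expect_equal(out[, 1:4], v)
  pre <- sweep((a %*% v) %*% lp$W, 2, lp$b, "+")
  hand <- pre * (pre > 0) + 0.01 * pre * (pre <= 0)
  expect_equal(out[, 5:10], hand, tolerance = 1e-10)

  # single node, identity FC: output is [v || LeakyReLU(v)]
  v1 <- matrix(c(-2, 3), 1, 2)
  id <- list(W = diag(2), b = c(0, 0))
  expect_equal(layer_forward(v1, matrix(1, 1, 1), id),
               matrix(c(-2, 3, -0.02, 3), 1, 4), ignore_attr = TRUE)

  expect_error(layer_forward(v, a[1:2, 1:2], lp), "dimension error")
})

test_that("forward pass yields probability rows and graph invariants hold", {
  pool <- make_pool(n_per_class = 12, d = 5, K = 3, seed = 10)
  std <- standardize_features(pool$features)
  cfg <- amgnn_config(k_shot = 4, n_query = 3, hidden = 8)
  ep <- sample_episode(std$features, pool$stages, pool$spec,
                       k_shot = 4, n_query = 3, seed = 20)
  params <- amgnn_init(5, 3, cfg, seed = 21)
  p <- amgnn_forward(ep, params, cfg)
  expect_equal(dim(p), c(3, 4))
  expect_equal(rowSums(p), rep(1, 3), tolerance = 1e-10, ignore_attr = TRUE)

  # invariants of the internal edge matrices on this episode
  v0 <- cbind(ep$node_features, copdgnn:::.label_block(ep))
  w <- edge_weight_matrix(v0, params$m1, cfg$leaky_slope)
  e <- edge_constraint_matrix(ep$risk_values, cfg$tau)
  expect_equal(w, t(w), ignore_attr = TRUE)
  expect_equal(e, t(e), ignore_attr = TRUE)
  expect_equal(diag(e), rep(1, nrow(e)), ignore_attr = TRUE)
  expect_equal(rowSums(adjacency(w, e)), rep(1, nrow(w)), tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("query probabilities are invariant to support-node permutation", {
  pool <- make_pool(n_per_class = 10, d = 4, K = 2, seed = 30)
  std <- standardize_features(pool$features)
  cfg <- amgnn_config(k_shot = 6, n_query = 2, hidden = 8)
  ep <- sample_episode(std$features, pool$stages, pool$spec,
                       k_shot = 6, n_query = 2, seed = 31)
  params <- amgnn_init(4, 2, cfg, seed = 32)
  p0 <- amgnn_forward(ep, params, cfg)

  set.seed(33)
  perm <- sample(length(ep$support_ids))
  ns <- length(ep$support_ids)
  ep2 <- ep
  ep2$support_ids <- ep$support_ids[perm]
  ep2$support_labels <- ep$support_labels[perm]
  ep2$node_features <- rbind(ep$node_features[perm, ], ep$node_features[-seq_len(ns), ])
  ep2$risk_values <- rbind(ep$risk_values[perm, ], ep$risk_values[-seq_len(ns), ])
  p1 <- amgnn_forward(ep2, params, cfg)
  expect_lt(max(abs(p0 - p1)), 1e-6)
})

test_that("disabling constraints equals an all-ones constraint matrix", {
  pool <- make_pool(n_per_class = 8, d = 4, K = 2, seed = 40)
  std <- standardize_features(pool$features)
  cfg_on <- amgnn_config(k_shot = 4, hidden = 6, use_constraints = TRUE)
  cfg_off <- amgnn_config(k_shot = 4, hidden = 6, use_constraints = FALSE)
  ep <- sample_episode(std$features, pool$stages, pool$spec,
                       k_shot = 4, n_query = 1, seed = 41)
  # make all risk rows identical so E is exactly all-ones
  ep$risk_values[] <- 0.5
  params <- amgnn_init(4, 2, cfg_on, seed = 42)
  expect_equal(amgnn_forward(ep, params, cfg_on),
               amgnn_forward(ep, params, cfg_off), tolerance = 1e-12)
})

test_that("analytic gradients match finite differences", {
  pool <- make_pool(n_per_class = 4, d = 3, K = 2, seed = 50)
  std <- standardize_features(pool$features)
  cfg <- amgnn_config(k_shot = 2, n_query = 2, hidden = 5)
  ep <- sample_episode(std$features, pool$stages, pool$spec,
                       k_shot = 2, n_query = 2, seed = 51)
  params <- amgnn_init(3, 2, cfg, seed = 52)
  # jitter all parameters off the LeakyReLU kinks (|v_i - v_i| = 0 puts the
  # zero-initialized metric biases exactly at the nondifferentiable point)
  set.seed(53)
  params <- copdgnn:::.tree_map(function(p) p + rnorm(length(p), sd = 0.05), params)
  lg <- copdgnn:::.amgnn_loss_grad(ep, params, cfg)
  eps <- 1e-6
  set.seed(54)
  for (grp in names(params)) {
    for (leaf in names(params[[grp]])) {
      arr <- params[[grp]][[leaf]]
      for (i in sample(length(arr), min(3, length(arr)))) {
        p2 <- params
        p2[[grp]][[leaf]][i] <- p2[[grp]][[leaf]][i] + eps
        lp <- copdgnn:::.amgnn_loss_grad(ep, p2, cfg)$loss
        p2[[grp]][[leaf]][i] <- p2[[grp]][[leaf]][i] - 2 * eps
        lm <- copdgnn:::.amgnn_loss_grad(ep, p2, cfg)$loss
        g_num <- (lp - lm) / (2 * eps)
        g_ana <- lg$grads[[grp]][[leaf]][i]
        expect_equal(g_ana, g_num, tolerance = 1e-4,
                     label = sprintf("grad %s$%s[%d]", grp, leaf, i))
      }
    }
  }
})

test_that("meta-training is a seeded no-op at 0 iterations and reduces loss on signal", {
  pool <- make_pool(n_per_class = 15, d = 4, K = 2, seed = 60)
  std <- standardize_features(pool$features)
  cfg0 <- amgnn_config(iterations = 0, k_shot = 4, hidden = 6, batch_size = 2,
                       seed = 7)
  m0 <- meta_train(std$features, pool$stages, pool$spec, cfg0)
  set.seed(7)
  ref <- amgnn_init(4, 2, cfg0)
  expect_identical(m0$params, ref)
  expect_length(m0$loss_history, 0)

  cfg <- amgnn_config(iterations = 40, batch_size = 8, k_shot = 4, hidden = 8,
                      seed = 8)
  m1 <- meta_train(std$features, pool$stages, pool$spec, cfg)
  expect_length(m1$loss_history, 40)
  expect_true(all(is.finite(m1$loss_history)))
  expect_lt(mean(tail(m1$loss_history, 10)), mean(head(m1$loss_history, 10)))

  # full determinism under fixed seed
  m2 <- meta_train(std$features, pool$stages, pool$spec, cfg)
  expect_identical(m1$loss_history, m2$loss_history)
  expect_identical(m1$params, m2$params)

  bad_spec <- build_combination(character(0), pool$spec$node_features)
  expect_error(meta_train(std$features, pool$stages, bad_spec, cfg),
               "configuration error")
})

test_that("prediction is deterministic per seed and sane on separable data", {
  pool <- make_pool(n_per_class = 15, d = 4, K = 2, seed = 70)
  std <- standardize_features(pool$features)
  cfg <- amgnn_config(iterations = 60, batch_size = 8, k_shot = 5, hidden = 8,
                      ensemble = 1, seed = 9)
  sp <- stratified_split(pool$stages, 0.8, seed = 71)
  tr <- sp$train
  te <- sp$test
  model <- meta_train(std$features[tr, ], pool$stages[tr], pool$spec, cfg)
  newx <- std$features[te, , drop = FALSE]
  p1 <- predict(model, newx, std$features[tr, ], pool$stages[tr], seed = 3)
  p2 <- predict(model, newx, std$features[tr, ], pool$stages[tr], seed = 3)
  expect_identical(p1, p2)
  expect_equal(rowSums(p1$probs), rep(1, length(te)), tolerance = 1e-10,
               ignore_attr = TRUE)
  # make_pool shifts node means by stage, so a trained model should beat chance
  expect_gt(mean(p1$stage == pool$stages[te]), 0.25)
})

test_that("model checkpoints round-trip with a JSON sidecar", {
  pool <- make_pool(n_per_class = 5, d = 3, K = 2, seed = 80)
  std <- standardize_features(pool$features)
  cfg <- amgnn_config(iterations = 2, batch_size = 2, k_shot = 2, hidden = 4,
                      seed = 10)
  model <- meta_train(std$features, pool$stages, pool$spec, cfg)
  path <- tempfile(fileext = ".rds")
  save_amgnn(model, path)
  expect_true(file.exists(paste0(path, ".json")))
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  expect_equal(side$K, 2)
  back <- load_amgnn(path)
  expect_identical(back$params, model$params)
})
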