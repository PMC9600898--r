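# The four-experiment evaluation grid. Experiment 1 benchmarks the six
# reference classifiers over feature sets {raw, lasso, glm, pca, lasso+pca,
# glm+pca}; Experiments 2-4 run the AMGNN with K = 2..6 risk factors drawn
# by PCA or GLM from either the raw or the Lasso-selected table, crossed
# with raw vs Lasso-selected node features:
#   Exp 2: risks from raw features, node features = raw.
#   Exp 3: risks from Lasso-selected features, node features = Lasso set.
#   Exp 4: risks from raw features, node features = Lasso set (the
#          combination-vector configuration).

.grid_row <- function(experiment, feature_source, selector, K, classifier,
                      m, seed) {
  data.frame(experiment = experiment, feature_source = feature_source,
             selector = selector, K = ifelse(is.na(K), NA_integer_, as.integer(K)),
             classifier = classifier, accuracy = m$accuracy,
             precision = m$precision_macro, recall = m$recall_macro,
             f1 = m$f1_macro, auc = m$auc_macro_ovr, seed = seed,
             stringsAsFactors = FALSE)
}

# Standardized PCA score columns appended to the design so PCA-derived risk
# factors can be addressed by name like any feature.
.append_pc_columns <- function(xaug, x_source, train_idx, n_comp, prefix) {
  pc <- pca_fuse(x_source, n_components = n_comp, fit_on = train_idx)
  sc <- pc$scores
  sds <- apply(sc[train_idx, , drop = FALSE], 2, stats::sd)
  sds[sds == 0] <- 1
  sc <- sweep(sc, 2, sds, "/")
  colnames(sc) <- sprintf("%s%d", prefix, seq_len(ncol(sc)))
  cbind(xaug, sc)
}

#' Run the experiment grid on a cohort
#'
#' Reproduces the structure of the four benchmark experiments on a supplied
#' cohort: a stratified 70/30 split, standardization and all feature
#' selection fitted on the training split only, then the classifier cells
#' described above. Infeasible cells are recorded as failures and the run
#' continues.
#'
#' @param cohort a `copd_cohort` (or list with `features` and `stages`).
#' @param feature_source label for the result rows (`"radiomics"` or
#'   `"cnn"`).
#' @param experiments subset of 1:4.
#' @param K_range risk-factor counts for experiments 2-4 (default 2:6).
#' @param classifiers reference classifiers for experiment 1.
#' @param amgnn an [amgnn_config()] for the AMGNN cells.
#' @param n_folds CV folds for reference-classifier model selection.
#' @param split_frac training fraction of the outer split.
#' @param seed master seed; all stage seeds derive from it.
#' @param out_dir optional directory: one CSV per experiment plus a JSON
#'   report, each embedding the config hash and master seed.
#' @return list with `results` (data.frame over all cells), `tables` (one
#'   data.frame per experiment), `failures` (data.frame of skipped cells),
#'   `selection` (lasso fit, glm ranking, split indices).
#' @export
run_experiment_grid <- function(cohort, feature_source = "radiomics",
                                experiments = 1:4, K_range = 2:6,
                                classifiers = baseline_names(),
                                amgnn = amgnn_config(),
                                n_folds = 5L, split_frac = 0.7, seed = 1L,
                                out_dir = NULL) {
  y <- as.integer(cohort$stages)
  split <- stratified_split(y, frac = split_frac, seed = derive_seed(seed, 1L))
  tr <- split$train
  te <- split$test
  std <- standardize_features(cohort$features, fit_on = tr)
  xs <- std$features
  y_tr <- y[tr]
  y_te <- y[te]

  lasso <- lasso_select(xs[tr, , drop = FALSE], y_tr, n_folds = 10L,
                        seed = derive_seed(seed, 2L))
  lasso_feats <- lasso$selected
  rank_raw <- glm_rank(xs[tr, , drop = FALSE], y_tr, K = ncol(xs))
  d_sel <- max(length(lasso_feats), 1L)

  xaug <- xs
  max_k <- max(K_range)
  n_pc_raw <- min(max(d_sel, max_k), length(tr) - 1L, ncol(xs))
  xaug <- .append_pc_columns(xaug, cohort$features, tr, n_pc_raw, "rawPC")
  if (length(lasso_feats) > 1L) {
    n_pc_sel <- min(max_k, length(lasso_feats), length(tr) - 1L)
    xaug <- .append_pc_columns(xaug, cohort$features[, lasso_feats, drop = FALSE],
                               tr, n_pc_sel, "selPC")
  }

  rows <- list()
  failures <- list()
  metrics_all <- list()
  cell <- 0L
  add_cell <- function(experiment, selector, K, classifier, fn) {
    cell <<- cell + 1L
    cell_seed <- derive_seed(seed, 100L + cell)
    res <- tryCatch(fn(cell_seed), error = function(e) e)
    tag <- sprintf("exp%d_%s_%s%s", experiment, selector, classifier,
                   ifelse(is.na(K), "", sprintf("_K%d", K)))
    if (inherits(res, "error")) {
      failures[[length(failures) + 1L]] <<- data.frame(
        experiment = experiment, selector = selector, K = K,
        classifier = classifier, message = conditionMessage(res),
        stringsAsFactors = FALSE)
    } else {
      metrics_all[[tag]] <<- res
      rows[[length(rows) + 1L]] <<- .grid_row(experiment, feature_source,
                                              selector, K, classifier, res,
                                              cell_seed)
    }
  }

  # -- Experiment 1: reference classifiers x feature sets ------------------
  if (1L %in% experiments) {
    glm_feats <- rank_raw$fits$feature[seq_len(min(d_sel, nrow(rank_raw$fits)))]
    pc_cols <- grep("^rawPC", colnames(xaug), value = TRUE)[seq_len(min(d_sel, n_pc_raw))]
    sets <- list(
      raw = colnames(xs),
      lasso = lasso_feats,
      glm = glm_feats,
      pca = pc_cols,
      lasso_pca = unique(c(lasso_feats, pc_cols)),
      glm_pca = unique(c(glm_feats, pc_cols))
    )
    for (sel in names(sets)) {
      cols <- sets[[sel]]
      for (clf in classifiers) {
        add_cell(1L, sel, NA_integer_, clf, function(cell_seed) {
          if (length(cols) == 0L) stop("empty feature set")
          factory <- make_baseline_factory(clf, seed = cell_seed)
          cv <- cross_validate(xaug[tr, cols, drop = FALSE], y_tr, factory,
                               n_folds = n_folds, seed = cell_seed)
          probs <- cv$best_model$predict(xaug[te, cols, drop = FALSE])
          compute_metrics(y_te, max.col(probs, ties.method = "first") - 1L, probs)
        })
      }
    }
  }

  # -- Experiments 2-4: AMGNN over K x risk-method x node-feature source ---
  amgnn_cell <- function(risk_names, node_names) {
    function(cell_seed) {
      if (length(node_names) == 0L) stop("empty node-feature set")
      if (length(risk_names) == 0L) stop("empty risk-factor set")
      cfg <- amgnn
      cfg$seed <- cell_seed
      spec <- build_combination(risk_names, node_names)
      model <- meta_train(xaug[tr, , drop = FALSE], y_tr, spec, cfg)
      pr <- stats::predict(model, xaug[te, , drop = FALSE],
                           train_features = xaug[tr, , drop = FALSE],
                           train_stages = y_tr, seed = derive_seed(cell_seed, 7L))
      compute_metrics(y_te, pr$stage, pr$probs)
    }
  }
  risk_names_for <- function(method, source_feats, pc_prefix, K) {
    if (method == "glm") {
      rk <- glm_rank(xs[tr, source_feats, drop = FALSE], y_tr,
                     K = min(K, length(source_feats)))
      rk$risk_factors
    } else {
      cols <- sprintf("%s%d", pc_prefix, seq_len(K))
      intersect(cols, colnames(xaug))
    }
  }
  exp_defs <- list(
    `2` = list(risk_src = "raw", nodes = colnames(xs)),
    `3` = list(risk_src = "sel", nodes = lasso_feats),
    `4` = list(risk_src = "raw", nodes = lasso_feats)
  )
  for (e in intersect(experiments, 2:4)) {
    def <- exp_defs[[as.character(e)]]
    for (method in c("pca", "glm")) {
      for (K in K_range) {
        src_feats <- if (def$risk_src == "raw") colnames(xs) else lasso_feats
        pc_prefix <- if (def$risk_src == "raw") "rawPC" else "selPC"
        add_cell(e, sprintf("%s_risk_%s", method, def$risk_src), K,
                 sprintf("amgnn_K%d", K), local({
                   m <- method; kk <- K; sf <- src_feats; pp <- pc_prefix
                   nodes <- def$nodes
                   function(cell_seed) {
                     rn <- risk_names_for(m, sf, pp, kk)
                     if (length(rn) < kk) stop(sprintf("grid cell infeasible: only %d risk factors available, need %d", length(rn), kk))
                     amgnn_cell(rn, nodes)(cell_seed)
                   }
                 }))
      }
    }
  }

  results <- if (length(rows) > 0L) do.call(rbind, rows) else NULL
  failures <- if (length(failures) > 0L) do.call(rbind, failures) else NULL
  tables <- if (!is.null(results)) split(results, results$experiment) else list()
  out <- list(results = results, tables = tables, failures = failures,
              selection = list(lasso = lasso, glm_ranking = rank_raw,
                               split = split, dropped = std$dropped),
              seed = seed)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    hash <- config_hash(list(seed = seed, experiments = experiments,
                             K_range = K_range, source = feature_source))
    for (e in names(tables)) {
      f <- file.path(out_dir, sprintf("experiment%s_%s.csv", e, feature_source))
      con <- file(f, "w")
      writeLines(sprintf("# config_hash=%s", hash), con)
      writeLines(sprintf("# master_seed=%d", seed), con)
      utils::write.csv(tables[[e]], con, row.names = FALSE)
      close(con)
    }
    jsonlite::write_json(
      list(config_hash = hash, master_seed = seed,
           results = results, failures = failures),
      file.path(out_dir, sprintf("grid_report_%s.json", feature_source)),
      auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  out
}
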