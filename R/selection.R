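#' Standardize a feature table
#'
#' Centres and scales every column using mean/SD estimated on a subset of
#' rows (typically the training split) and applies the same transform to all
#' rows, so test rows never leak into the fit. Columns with zero variance on
#' the fitting rows are dropped and reported.
#'
#' @param x numeric matrix (samples x features) with dimnames.
#' @param fit_on row indices (or rownames) used to estimate mean/SD;
#'   default all rows.
#' @return list with `features` (transformed matrix, dropped columns
#'   removed), `center`, `scale` (named vectors over retained columns) and
#'   `dropped` (names of zero-variance columns).
#' @export
standardize_features <- function(x, fit_on = NULL) {
  if (is.null(fit_on)) fit_on <- seq_len(nrow(x))
  if (length(fit_on) == 0L) stop("fit_on must be non-empty", call. = FALSE)
  xf <- x[fit_on, , drop = FALSE]
  ctr <- colMeans(xf)
  scl <- apply(xf, 2, stats::sd)
  keep <- is.finite(scl) & scl > 0
  if (!any(keep)) stop("empty table: all columns have zero variance on the fitting rows", call. = FALSE)
  dropped <- colnames(x)[!keep]
  xs <- sweep(x[, keep, drop = FALSE], 2, ctr[keep], "-")
  xs <- sweep(xs, 2, scl[keep], "/")
  list(features = xs, center = ctr[keep], scale = scl[keep], dropped = dropped)
}

# glmnet-convention lambda_max for a standardized design with intercept
.lambda_max <- function(x, y) {
  max(abs(crossprod(x, y - mean(y)))) / nrow(x)
}

#' Lasso node-feature selection with k-fold cross-validation
#'
#' Fits the squared-error L1 path \eqn{\sum_i (y_i - \beta_0 - \sum_j
#' \beta_j x_{ij})^2 + \lambda \sum_j |\beta_j|} over a geometric lambda path
#' (100 points spanning four decades below \eqn{\lambda_{max}}) and picks
#' \eqn{\lambda^*} by minimum mean cross-validated squared error over
#' stage-stratified folds. The GOLD stage enters as an ordinal response 0-3.
#' Features with a non-zero coefficient at \eqn{\lambda^*} become the node
#' features of the combination vector.
#'
#' Fitting is delegated to \pkg{glmnet} (gaussian family, `standardize =
#' FALSE`: the design is expected to be standardized already).
#'
#' @param x standardized numeric matrix (samples x features).
#' @param y integer stage labels 0..3 (treated as a continuous response).
#' @param n_folds number of CV folds (default 10).
#' @param seed RNG seed controlling fold assignment.
#' @param lambda optional fixed penalty; when given, no cross-validation is
#'   performed and the fit at exactly this lambda is returned.
#' @param nlambda,lambda_min_ratio path resolution and depth.
#' @return An object of class `lasso_fit`: `lambda_path`, `lambda_star`,
#'   `beta0`, `beta` (named coefficient vector), `selected` (names with
#'   non-zero coefficient), `cv_folds`, and `cvm` (mean CV error per lambda,
#'   `NULL` for a fixed-lambda fit).
#' @export
lasso_select <- function(x, y, n_folds = 10L, seed = 1L, lambda = NULL,
                         nlambda = 100L, lambda_min_ratio = 1e-4) {
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    stop("data error: non-finite values in the design or response", call. = FALSE)
  }
  y <- as.numeric(y)
  lmax <- .lambda_max(x, y)
  if (lmax <= 0) lmax <- 1
  path <- exp(seq(log(lmax), log(lmax * lambda_min_ratio), length.out = nlambda))
  if (!is.null(lambda)) {
    fit_path <- sort(unique(c(path, lambda)), decreasing = TRUE)
    fit <- glmnet::glmnet(x, y, family = "gaussian", alpha = 1,
                          lambda = fit_path, standardize = FALSE,
                          thresh = 1e-12)
    cf <- as.vector(suppressWarnings(
      stats::coef(fit, s = lambda, exact = TRUE, x = x, y = y)))
    lambda_star <- lambda
    cvm <- NULL
    cv_folds <- 0L
  } else {
    if (n_folds < 2L || n_folds > nrow(x)) {
      stop("fold error: n_folds must be in [2, n]", call. = FALSE)
    }
    foldid <- stratified_folds(y, n_folds, seed = seed)
    cvfit <- glmnet::cv.glmnet(x, y, family = "gaussian", alpha = 1,
                               lambda = path, foldid = foldid,
                               standardize = FALSE, thresh = 1e-10)
    cf <- as.vector(stats::coef(cvfit, s = "lambda.min"))
    lambda_star <- cvfit$lambda.min
    cvm <- cvfit$cvm
    cv_folds <- as.integer(n_folds)
  }
  beta <- cf[-1]
  names(beta) <- colnames(x)
  structure(list(lambda_path = path, lambda_star = lambda_star,
                 beta0 = cf[1], beta = beta,
                 selected = colnames(x)[beta != 0],
                 cv_folds = cv_folds, cvm = cvm),
            class = "lasso_fit")
}

#' @export
print.lasso_fit <- function(x, ...) {
  cat(sprintf("lasso_fit: lambda* = %.5g, %d features selected (%d-fold CV)\n",
              x$lambda_star, length(x$selected), x$cv_folds))
  invisible(x)
}

#' Rank features by univariate GLM R-squared
#'
#' Fits one univariate identity-link gaussian regression of the ordinal
#' stage on each feature and ranks features by \eqn{R^2 = 1 - SSE/SST}
#' (equivalently the squared Pearson correlation), descending; ties break by
#' feature-name lexicographic order. The top `K` features are the risk
#' factors of the combination vector. Zero-variance features get
#' \eqn{R^2 = 0}.
#'
#' @param x numeric matrix (samples x features).
#' @param y integer stage labels 0..3.
#' @param K number of risk factors to return.
#' @return list of class `glm_rank` with `fits` (data.frame `feature`,
#'   `beta0`, `beta`, `r_squared`, sorted by descending R-squared) and
#'   `risk_factors` (top-K feature names).
#' @export
glm_rank <- function(x, y, K = 3L) {
  if (K < 1L || K > ncol(x)) {
    stop("selection error: K must be in [1, number of usable features]", call. = FALSE)
  }
  y <- as.numeric(y)
  n <- nrow(x)
  mx <- colMeans(x)
  my <- mean(y)
  vx <- colSums(sweep(x, 2, mx, "-")^2) / (n - 1)
  vy <- sum((y - my)^2) / (n - 1)
  cxy <- as.vector(crossprod(sweep(x, 2, mx, "-"), y - my)) / (n - 1)
  beta <- ifelse(vx > 0, cxy / vx, 0)
  r2 <- ifelse(vx > 0 & vy > 0, cxy^2 / (vx * vy), 0)
  fits <- data.frame(feature = colnames(x), beta0 = my - beta * mx, beta = beta,
                     r_squared = r2, row.names = NULL, stringsAsFactors = FALSE)
  fits <- fits[order(-fits$r_squared, fits$feature), , drop = FALSE]
  rownames(fits) <- NULL
  structure(list(fits = fits, risk_factors = fits$feature[seq_len(K)]),
            class = "glm_rank")
}

#' PCA feature fusion
#'
#' Projects the (internally standardized) feature table onto its leading
#' principal components, the fusion comparator used alongside Lasso and GLM
#' selection. The rotation is estimated on `fit_on` rows and applied to all
#' rows.
#'
#' @param x numeric matrix (samples x features).
#' @param n_components number of components, at most `min(|fit_on| - 1, p)`.
#' @param fit_on rows used to fit the rotation (default all).
#' @return list of class `pca_fusion` with `scores` (n x n_components matrix,
#'   columns `PC1`...), `rotation`, `center`, `scale`, `sdev`, `dropped`.
#' @export
pca_fuse <- function(x, n_components, fit_on = NULL) {
  if (is.null(fit_on)) fit_on <- seq_len(nrow(x))
  std <- standardize_features(x, fit_on = fit_on)
  p <- ncol(std$features)
  if (n_components > min(length(fit_on) - 1L, p)) {
    stop("dimension error: n_components exceeds min(n - 1, p)", call. = FALSE)
  }
  pc <- stats::prcomp(std$features[fit_on, , drop = FALSE],
                      center = FALSE, scale. = FALSE)
  rot <- pc$rotation[, seq_len(n_components), drop = FALSE]
  scores <- std$features %*% rot
  colnames(scores) <- sprintf("PC%d", seq_len(n_components))
  structure(list(scores = scores, rotation = rot, center = std$center,
                 scale = std$scale, sdev = pc$sdev, dropped = std$dropped),
            class = "pca_fusion")
}

#' Build a combination-vector specification
#'
#' The combination vector concatenates K risk factors (edge-constraint
#' inputs) with d node features (per-node representation); a feature may
#' appear in both roles.
#'
#' @param risk_factors ordered character vector of K risk-factor names.
#' @param node_features ordered character vector of d node-feature names.
#' @return object of class `combination_spec` with fields `risk_factors`,
#'   `node_features`, `K`, `d`.
#' @export
build_combination <- function(risk_factors, node_features) {
  risk_factors <- as.character(risk_factors)
  node_features <- as.character(node_features)
  structure(list(risk_factors = risk_factors, node_features = node_features,
                 K = length(risk_factors), d = length(node_features)),
            class = "combination_spec")
}

#' @export
print.combination_spec <- function(x, ...) {
  cat(sprintf("combination_spec: (%d + %d) = K risk factors + d node features\n",
              x$K, x$d))
  invisible(x)
}

#' Write/read a combination-vector spec as JSON
#'
#' @param spec a [build_combination()] object.
#' @param path file path.
#' @return `read_combination` returns a `combination_spec`.
#' @export
write_combination <- function(spec, path) {
  jsonlite::write_json(list(risk_factors = spec$risk_factors,
                            node_features = spec$node_features),
                       path, pretty = TRUE)
  invisible(path)
}

#' @rdname write_combination
#' @export
read_combination <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$risk_factors)) obj$risk_factors <- character(0)
  if (is.null(obj$node_features)) obj$node_features <- character(0)
  build_combination(obj$risk_factors, obj$node_features)
}
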