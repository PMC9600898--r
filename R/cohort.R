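#' Specify a synthetic radiomics cohort
#'
#' Defines the statistical shape of a simulated participant-by-feature table
#' emulating a lung radiomics cohort: four ordered GOLD stages (0, I, II,
#' III-IV merged) with monotone class-mean shifts on a subset of informative
#' features, and correlated feature blocks mimicking the redundancy of
#' wavelet/LoG-derived feature families.
#'
#' Each feature value is `mu + noise_sd * (sqrt(rho) * f_b + sqrt(1 - rho) * e)`
#' where `f_b` is a standard-normal factor shared by all features of block `b`,
#' `e` is idiosyncratic standard normal, and `mu = stage * effect_size` for
#' informative features (0 otherwise). Within-class SD is `noise_sd`, so
#' `effect_size` is the between-adjacent-stage mean shift in units of the
#' within-class SD when `noise_sd = 1`. Pairwise within-block correlation is
#' `rho`.
#'
#' @param n_per_class integer(4), participants per GOLD stage 0..3.
#'   Default 129, 108, 121, 107 (total 465).
#' @param p_total total number of features (default 1316).
#' @param p_informative number of features carrying the stage signal
#'   (placed at seeded-random column positions).
#' @param effect_size non-negative mean shift between adjacent stages, in
#'   units of `noise_sd`.
#' @param block_size features per correlated block (default 47; 1316 = 28
#'   blocks of 47).
#' @param rho within-block pairwise correlation, in [0, 1).
#' @param noise_sd within-class standard deviation (> 0).
#' @param seed integer RNG seed; identical spec + seed gives bit-identical
#'   cohorts.
#' @return An object of class `cohort_spec`.
#' @seealso [generate_cohort()]
#' @export
cohort_spec <- function(n_per_class = c(129L, 108L, 121L, 107L),
                        p_total = 1316L,
                        p_informative = 100L,
                        effect_size = 0.5,
                        block_size = 47L,
                        rho = 0.5,
                        noise_sd = 1,
                        seed = 1L) {
  spec <- list(
    n_per_class = as.integer(n_per_class), p_total = as.integer(p_total),
    p_informative = as.integer(p_informative), effect_size = effect_size,
    block_size = as.integer(block_size), rho = rho, noise_sd = noise_sd,
    seed = as.integer(seed)
  )
  class(spec) <- "cohort_spec"
  validate_cohort_spec(spec)
  spec
}

validate_cohort_spec <- function(spec) {
  if (length(spec$n_per_class) != 4L || any(spec$n_per_class < 1L)) {
    stop("invalid cohort spec: n_per_class must be 4 positive integers", call. = FALSE)
  }
  if (spec$p_total < 1L) stop("invalid cohort spec: p_total must be positive", call. = FALSE)
  if (spec$p_informative < 0L || spec$p_informative > spec$p_total) {
    stop("invalid cohort spec: p_informative must lie in [0, p_total]", call. = FALSE)
  }
  if (spec$effect_size < 0) stop("invalid cohort spec: effect_size must be non-negative", call. = FALSE)
  if (spec$block_size < 1L) stop("invalid cohort spec: block_size must be positive", call. = FALSE)
  if (spec$rho < 0 || spec$rho >= 1) stop("invalid cohort spec: rho must be in [0, 1)", call. = FALSE)
  if (spec$noise_sd <= 0) stop("invalid cohort spec: noise_sd must be positive", call. = FALSE)
  invisible(spec)
}

# Correlated block noise: one latent factor per block with loading sqrt(rho).
.block_noise <- function(n, p, block_size, rho) {
  block_id <- ceiling(seq_len(p) / block_size)
  n_blocks <- max(block_id)
  e <- matrix(stats::rnorm(n * p), n, p)
  if (rho > 0) {
    f <- matrix(stats::rnorm(n * n_blocks), n, n_blocks)
    sqrt(rho) * f[, block_id, drop = FALSE] + sqrt(1 - rho) * e
  } else {
    e
  }
}

.simulate_feature_table <- function(stages, p_total, p_informative, effect_size,
                                    block_size, rho, noise_sd, feature_names) {
  n <- length(stages)
  informative <- if (p_informative > 0L) sort(sample.int(p_total, p_informative)) else integer(0)
  x <- noise_sd * .block_noise(n, p_total, block_size, rho)
  if (length(informative) > 0L && effect_size > 0) {
    shift <- outer(stages * (effect_size * noise_sd), rep(1, length(informative)))
    x[, informative] <- x[, informative] + shift
  }
  colnames(x) <- feature_names
  list(values = x, informative = feature_names[informative])
}

#' Generate a synthetic radiomics cohort
#'
#' Draws a participant-by-feature table plus 4-level GOLD stage labels from a
#' [cohort_spec()]. Sample IDs are zero-padded (`"P0001"`, ...); stages are
#' coded 0-3 with 3 the merged III-IV stratum.
#'
#' @param spec a [cohort_spec()].
#' @return A list of class `copd_cohort` with elements
#'   \describe{
#'     \item{features}{numeric matrix n x p, rownames = sample IDs.}
#'     \item{stages}{named integer vector in 0..3, aligned with `features`.}
#'     \item{ground_truth}{character vector naming the informative columns.}
#'     \item{spec}{the generating spec.}
#'   }
#' @examples
#' coh <- generate_cohort(cohort_spec(n_per_class = c(10, 10, 10, 10),
#'                                    p_total = 50, p_informative = 5,
#'                                    effect_size = 1, seed = 7))
#' dim(coh$features)
#' @export
generate_cohort <- function(spec) {
  validate_cohort_spec(spec)
  set.seed(spec$seed)
  stages <- rep(0:3, times = spec$n_per_class)
  n <- length(stages)
  ids <- sprintf("P%04d", seq_len(n))
  fnames <- sprintf("feat%04d", seq_len(spec$p_total))
  sim <- .simulate_feature_table(stages, spec$p_total, spec$p_informative,
                                 spec$effect_size, spec$block_size, spec$rho,
                                 spec$noise_sd, fnames)
  x <- sim$values
  rownames(x) <- ids
  names(stages) <- ids
  structure(list(features = x, stages = stages,
                 ground_truth = sim$informative, spec = spec),
            class = "copd_cohort")
}

#' @export
print.copd_cohort <- function(x, ...) {
  cat(sprintf("copd_cohort: %d participants x %d features\n",
              nrow(x$features), ncol(x$features)))
  cat("  per stage:", paste(table(factor(x$stages, levels = 0:3)), collapse = "/"), "\n")
  cat(sprintf("  informative features: %d\n", length(x$ground_truth)))
  invisible(x)
}

#' Emulate flattened 3D-CNN feature maps
#'
#' Generates a table whose columns emulate `n_maps` feature maps of shape
#' `map_shape` flattened per participant (e.g. 512 maps of 3 x 3 x 3 give
#' 13,824 columns). The voxels of one map form one correlated block; the
#' noise + class-shift model is the one used by [generate_cohort()].
#'
#' @param n number of participants (ignored when `stages` is given).
#' @param n_maps number of feature maps.
#' @param map_shape integer(3) spatial shape of each map.
#' @param seed RNG seed.
#' @param stages optional integer vector of stage labels 0..3; when `NULL`
#'   the table is unlabelled pure noise (no class shift).
#' @param effect_size,p_informative,rho,noise_sd as in [cohort_spec()].
#' @return list with `features` (n x n_maps*prod(map_shape) matrix) and
#'   `ground_truth` (informative column names, possibly empty).
#' @export
generate_cnn_like_features <- function(n, n_maps = 512L, map_shape = c(3L, 3L, 3L),
                                       seed = 1L, stages = NULL,
                                       effect_size = 0, p_informative = 0L,
                                       rho = 0.5, noise_sd = 1) {
  if (!is.null(stages)) n <- length(stages)
  if (n < 1L || n_maps < 1L || length(map_shape) != 3L || any(map_shape < 1L)) {
    stop("invalid cnn feature spec: all dimensions must be positive", call. = FALSE)
  }
  block <- prod(as.integer(map_shape))
  p <- as.integer(n_maps) * block
  if (p_informative < 0L || p_informative > p) {
    stop("invalid cnn feature spec: p_informative must lie in [0, p_total]", call. = FALSE)
  }
  set.seed(seed)
  if (is.null(stages)) stages <- rep(0L, n)
  fnames <- sprintf("cnn_m%04d_v%02d", rep(seq_len(n_maps), each = block),
                    rep(seq_len(block), times = n_maps))
  sim <- .simulate_feature_table(stages, p, as.integer(p_informative),
                                 effect_size, block, rho, noise_sd, fnames)
  x <- sim$values
  rownames(x) <- sprintf("P%04d", seq_len(n))
  list(features = x, ground_truth = sim$informative)
}

#' Stratified train/test split
#'
#' Splits samples into train and test fractions stratified by stage, the
#' split used throughout the pipeline (default 70/30).
#'
#' @param stages integer vector of stage labels.
#' @param frac training fraction in (0, 1).
#' @param seed RNG seed.
#' @return list with integer index vectors `train` and `test`.
#' @export
stratified_split <- function(stages, frac = 0.7, seed = 1L) {
  if (frac <= 0 || frac >= 1) stop("frac must be in (0, 1)", call. = FALSE)
  set.seed(seed)
  train <- integer(0)
  for (cl in sort(unique(stages))) {
    idx <- which(stages == cl)
    n_tr <- max(1L, round(length(idx) * frac))
    train <- c(train, sample(idx, n_tr))
  }
  train <- sort(train)
  list(train = train, test = setdiff(seq_along(stages), train))
}

#' Stratified cross-validation fold assignment
#'
#' Assigns each sample to one of `k` folds such that every fold contains
#' every class (error if any class has fewer than `k` members).
#'
#' @param y class labels.
#' @param k number of folds.
#' @param seed RNG seed.
#' @return integer vector of fold ids in 1..k, one per sample.
#' @export
stratified_folds <- function(y, k, seed = 1L) {
  if (k < 2L) stop("need at least 2 folds", call. = FALSE)
  counts <- table(y)
  if (any(counts < k)) {
    bad <- names(counts)[counts < k][1]
    stop(sprintf("stratification error: class %s has fewer than %d samples", bad, k),
         call. = FALSE)
  }
  set.seed(seed)
  fold <- integer(length(y))
  for (cl in names(counts)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep(seq_len(k), length.out = length(idx))
  }
  fold
}
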