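# Table and config I/O for the pipeline. CSV dialect: header row, column 1
# `sample_id`, last column `gold_stage` in {0,1,2,3}, remaining columns
# numeric features; UTF-8, comma separator, '.' decimal. Leading '#' lines
# carry run provenance (config hash, master seed) and are skipped on read.

.mulmod32 <- function(a, b) {
  lo <- a %% 65536
  hi <- a %/% 65536
  (((hi * b) %% 65536) * 65536 + lo * b) %% 4294967296
}

# FNV-1a 32-bit hash of a string, as 8 hex digits.
config_hash <- function(x) {
  if (!is.character(x)) x <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA)
  bytes <- utf8ToInt(paste(x, collapse = ""))
  h <- 2166136261
  for (b in bytes) {
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), as.integer(b))
    h <- .mulmod32(h, 16777619)
  }
  paste0(sprintf("%04x", h %/% 65536), sprintf("%04x", h %% 65536))
}

# Deterministic per-stage seed derivation from one master seed.
derive_seed <- function(master, index) {
  as.integer((as.numeric(master) * 7919 + as.numeric(index) * 104729) %% 2147483647)
}

#' Write a feature table with stage labels as CSV
#'
#' @param features numeric matrix (samples x features) with dimnames.
#' @param stages integer stages 0..3 aligned with rows.
#' @param path output path.
#' @param manifest optional named list written as leading `# key=value`
#'   comment lines (e.g. config hash and master seed).
#' @export
write_feature_table <- function(features, stages, path, manifest = NULL) {
  df <- data.frame(sample_id = rownames(features), features,
                   gold_stage = as.integer(stages),
                   check.names = FALSE, stringsAsFactors = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(manifest)) {
    for (k in names(manifest)) {
      writeLines(sprintf("# %s=%s", k, manifest[[k]]), con)
    }
  }
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a feature table with stage labels from CSV
#'
#' Validates the dialect written by [write_feature_table()]: a `sample_id`
#' column first, a `gold_stage` column (values 0-3) last, unique sample ids,
#' and numeric feature cells.
#'
#' @param path CSV path.
#' @return list with `features` (numeric matrix, rownames = sample ids) and
#'   `stages` (named integer vector).
#' @export
read_feature_table <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, comment.char = "#",
                        stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(df)) stop("format error: missing `sample_id` column", call. = FALSE)
  if (!"gold_stage" %in% names(df)) stop("format error: missing `gold_stage` column", call. = FALSE)
  ids <- as.character(df$sample_id)
  if (anyDuplicated(ids)) stop("format error: duplicate sample_id values", call. = FALSE)
  stage_raw <- df$gold_stage
  stages <- suppressWarnings(as.integer(stage_raw))
  bad <- which(is.na(stages) | stages < 0L | stages > 3L)
  if (length(bad) > 0L) {
    stop(sprintf("parse error: gold_stage value '%s' at row %d (valid range 0-3)",
                 stage_raw[bad[1]], bad[1]), call. = FALSE)
  }
  feat_cols <- setdiff(names(df), c("sample_id", "gold_stage"))
  x <- matrix(NA_real_, nrow(df), length(feat_cols),
              dimnames = list(ids, feat_cols))
  for (j in seq_along(feat_cols)) {
    col <- df[[feat_cols[j]]]
    v <- suppressWarnings(as.numeric(col))
    bad <- which(is.na(v) & !is.na(col))
    if (length(bad) > 0L || anyNA(v)) {
      r <- if (length(bad) > 0L) bad[1] else which(is.na(v))[1]
      stop(sprintf("parse error: non-numeric feature cell at row %d, column '%s'",
                   r, feat_cols[j]), call. = FALSE)
    }
    x[, j] <- v
  }
  names(stages) <- ids
  list(features = x, stages = stages)
}

#' Write ground-truth informative feature names
#'
#' One feature name per line, plain text.
#'
#' @param names character vector.
#' @param path output path.
#' @export
write_ground_truth <- function(names, path) {
  writeLines(names, path)
  invisible(path)
}

#' Read / write a run configuration (JSON)
#'
#' Configurations round-trip losslessly through their JSON form.
#'
#' @param config named list.
#' @param path file path.
#' @export
write_run_config <- function(config, path) {
  jsonlite::write_json(config, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
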