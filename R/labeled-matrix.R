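#' Samples-by-features intensity matrix with sample metadata
#'
#' The central data container of the pipeline: a non-negative linear-scale
#' intensity matrix (normalized spot volumes for 2D-DIGE, cluster intensities
#' for SELDI) with one row per sample, plus per-sample metadata describing the
#' irradiation design: dose (Gy), day post-irradiation, experimental series
#' (batch), and whether the sample is a pooled QC replicate.
#'
#' @param values numeric matrix, samples x features, non-negative, no missing
#'   values.
#' @param feature_ids character vector, one id per column.
#' @param meta data.frame with columns `sample_id`, `dose_gy`, `day`, `batch`,
#'   `is_qc_pool`; one row per sample; `sample_id` unique.
#' @return an object of class `labeled_matrix`.
#' @export
labeled_matrix <- function(values, feature_ids, meta) {
  values <- as.matrix(values)
  if (!is.numeric(values)) abort("values must be numeric")
  if (anyNA(values)) abort("values must not contain missing entries")
  required <- c("sample_id", "dose_gy", "day", "batch", "is_qc_pool")
  missing_cols <- setdiff(required, names(meta))
  if (length(missing_cols))
    abort("metadata missing column(s): %s", paste(missing_cols, collapse = ", "))
  if (nrow(values) != nrow(meta))
    abort("values has %d rows but meta has %d", nrow(values), nrow(meta))
  if (ncol(values) != length(feature_ids))
    abort("values has %d columns but %d feature_ids given",
          ncol(values), length(feature_ids))
  if (anyDuplicated(meta$sample_id))
    abort("duplicate sample_id: %s",
          paste(unique(meta$sample_id[duplicated(meta$sample_id)]), collapse = ", "))
  meta$sample_id <- as.character(meta$sample_id)
  meta$is_qc_pool <- as.logical(meta$is_qc_pool)
  rownames(values) <- meta$sample_id
  colnames(values) <- feature_ids
  structure(list(values = values,
                 feature_ids = as.character(feature_ids),
                 meta = meta[, required, drop = FALSE]),
            class = "labeled_matrix")
}

#' @export
print.labeled_matrix <- function(x, ...) {
  n_qc <- sum(x$meta$is_qc_pool)
  cat(sprintf("labeled_matrix: %d samples x %d features (%d QC pool)\n",
              nrow(x$values), ncol(x$values), n_qc))
  tab <- table(dose_gy = x$meta$dose_gy[!x$meta$is_qc_pool],
               day = x$meta$day[!x$meta$is_qc_pool])
  print(tab)
  invisible(x)
}

#' @export
dim.labeled_matrix <- function(x) dim(x$values)

#' Subset a labeled matrix by samples and/or features
#'
#' @param x a `labeled_matrix`.
#' @param samples logical/integer/character index over rows.
#' @param features logical/integer/character index over columns.
#' @return a `labeled_matrix`.
#' @export
lm_subset <- function(x, samples = NULL, features = NULL) {
  stopifnot(inherits(x, "labeled_matrix"))
  if (is.null(samples)) samples <- seq_len(nrow(x$values))
  if (is.null(features)) features <- seq_len(ncol(x$values))
  labeled_matrix(x$values[samples, features, drop = FALSE],
                 colnames(x$values[, features, drop = FALSE]),
                 x$meta[samples, , drop = FALSE])
}

#' Drop QC-pool rows (group statistics never see QC replicates)
#' @param x a `labeled_matrix`.
#' @return a `labeled_matrix` without QC rows.
#' @export
drop_qc <- function(x) {
  stopifnot(inherits(x, "labeled_matrix"))
  lm_subset(x, samples = !x$meta$is_qc_pool)
}

#' Write a labeled matrix to TSV
#'
#' Layout: one row per sample; columns `sample_id`, `dose_gy`, `day`, `batch`,
#' `is_qc_pool`, then one column per feature.  Values are written with full
#' double precision (`%.15g`), so a read/write round trip is lossless to
#' ~1e-15 relative error.
#'
#' @param x a `labeled_matrix`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_labeled_matrix <- function(x, path) {
  stopifnot(inherits(x, "labeled_matrix"))
  df <- cbind(x$meta,
              as.data.frame(apply(x$values, 2, function(v) sprintf("%.15g", v)),
                            check.names = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a labeled matrix from TSV
#'
#' Inverse of [write_labeled_matrix()].  Errors name the offending row or
#' column: a missing metadata column, a duplicated `sample_id`, or a
#' non-numeric intensity cell.
#'
#' @param path TSV file produced by [write_labeled_matrix()] (or compatible).
#' @return a `labeled_matrix`.
#' @export
read_labeled_matrix <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          colClasses = "character")
  required <- c("sample_id", "dose_gy", "day", "batch", "is_qc_pool")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    abort("%s: missing metadata column(s): %s", path,
          paste(missing_cols, collapse = ", "))
  dup <- unique(df$sample_id[duplicated(df$sample_id)])
  if (length(dup))
    abort("%s: duplicate sample_id: %s", path, paste(dup, collapse = ", "))
  feat_cols <- setdiff(names(df), required)
  vals <- matrix(NA_real_, nrow(df), length(feat_cols))
  for (j in seq_along(feat_cols)) {
    v <- suppressWarnings(as.numeric(df[[feat_cols[j]]]))
    bad <- which(is.na(v) & !is.na(df[[feat_cols[j]]]))
    if (length(bad))
      abort("%s: non-numeric value in column '%s', row %d ('%s')",
            path, feat_cols[j], bad[1], df[[feat_cols[j]]][bad[1]])
    vals[, j] <- v
  }
  meta <- data.frame(sample_id = df$sample_id,
                     dose_gy = as.numeric(df$dose_gy),
                     day = as.integer(df$day),
                     batch = as.integer(df$batch),
                     is_qc_pool = as.logical(df$is_qc_pool),
                     stringsAsFactors = FALSE)
  labeled_matrix(vals, feat_cols, meta)
}
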