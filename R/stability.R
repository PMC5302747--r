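#' Parameters for PLS-DA importance-frequency stability selection
#'
#' Defaults follow the study's resampling recipe: 10 repeated random 70/30
#' learning/test splits, the 30 highest-VIP variables recorded per repeat,
#' and "good" variables defined as those recurring in at least 8 of the 10
#' draws.
#'
#' @param n_repeats number of resampled fits (default 10).
#' @param train_frac learning-sample fraction (default 0.70).
#' @param top_k variables recorded per repeat (default 30).
#' @param min_freq minimum recurrence count for selection (default 8).
#' @param n_components PLS components (default 2).
#' @param seed master seed; repeat r uses substream `("plsda", r)`.
#' @return a `pls_select_params` list.
#' @export
pls_select_params <- function(n_repeats = 10L, train_frac = 0.70, top_k = 30L,
                              min_freq = 8L, n_components = 2L, seed = 1L) {
  if (min_freq > n_repeats) abort("min_freq must be <= n_repeats")
  if (train_frac <= 0 || train_frac >= 1) abort("train_frac must be in (0, 1)")
  structure(list(n_repeats = as.integer(n_repeats), train_frac = train_frac,
                 top_k = as.integer(top_k), min_freq = as.integer(min_freq),
                 n_components = as.integer(n_components),
                 seed = as.integer(seed)),
            class = "pls_select_params")
}

#' Parameters for Random-Forest importance-frequency stability selection
#'
#' Defaults follow the study's recipe: each elementary analysis grows 1,000
#' trees, each split drawn from 20 random candidate variables, on a
#' bootstrap sample of the full size; the 10 most important variables (mean
#' Gini impurity decrease) are recorded; the elementary analysis is repeated
#' 30 times with fresh random streams and variables are selected by their
#' top-10 recurrence count.  The retention threshold is a free parameter
#' (the recipe reports 4-10 selected variables but no cut); default 24/30,
#' an 80% recurrence.
#'
#' @param n_trees trees per elementary analysis (default 1000).
#' @param mtry candidate variables per split (default 20).
#' @param n_iterations elementary analyses (default 30).
#' @param top_k variables recorded per iteration (default 10).
#' @param retain_min_count minimum recurrence count (default 24).
#' @param seed master seed; iteration i uses substream `("rf", i)`.
#' @return an `rf_select_params` list.
#' @export
rf_select_params <- function(n_trees = 1000L, mtry = 20L, n_iterations = 30L,
                             top_k = 10L, retain_min_count = 24L, seed = 1L) {
  if (retain_min_count > n_iterations)
    abort("retain_min_count must be <= n_iterations")
  structure(list(n_trees = as.integer(n_trees), mtry = as.integer(mtry),
                 n_iterations = as.integer(n_iterations),
                 top_k = as.integer(top_k),
                 retain_min_count = as.integer(retain_min_count),
                 seed = as.integer(seed)),
            class = "rf_select_params")
}

# canonical predictor matrix: log scale, features in sorted-id order so both
# selectors are invariant to the column order of the input
canonical_predictors <- function(m, log_transform = TRUE) {
  stopifnot(inherits(m, "labeled_matrix"))
  X <- if (log_transform) {
    if (any(m$values <= 0)) abort("log transform requires positive intensities")
    log(m$values)
  } else m$values
  X[, order(colnames(X)), drop = FALSE]
}

# stratified train/test split: per class, round(train_frac * n_class) rows
stratified_split <- function(y, train_frac) {
  train <- integer(0)
  for (lv in levels(y)) {
    rows <- which(y == lv)
    n_tr <- round(train_frac * length(rows))
    if (n_tr < 2 || length(rows) - n_tr < 1)
      abort("stratification impossible: class '%s' too small", lv)
    train <- c(train, sample(rows, n_tr))
  }
  sort(train)
}

new_selection_result <- function(method, counts, selected, params,
                                 confusions = NULL) {
  structure(list(method = method, counts = counts, selected = selected,
                 params = params, confusions = confusions),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  n_rep <- if (x$method == "plsda") x$params$n_repeats else x$params$n_iterations
  cat(sprintf("selection_result (%s): %d/%d features selected\n",
              x$method, length(x$selected), length(x$counts)))
  if (length(x$selected)) {
    sel <- sort(x$counts[x$selected], decreasing = TRUE)
    for (nm in names(sel))
      cat(sprintf("  %-16s %d/%d\n", nm, sel[nm], n_rep))
  }
  invisible(x)
}

#' PLS-DA VIP stability selection over repeated random splits
#'
#' For each repeat: a stratified random 70/30 learning/test split, a PLS-DA
#' fit on the learning sample, the `top_k` variables by VIP recorded, and
#' the learning/test confusion matrices stored.  Variables recurring in at
#' least `min_freq` of the repeats are the "good" variables.
#'
#' @param m a [labeled_matrix()] (QC rows dropped).
#' @param labels two-level factor over the non-QC samples (each class >= 4).
#' @param params a [pls_select_params()].
#' @return a `selection_result` with per-feature counts, the selected ids,
#'   and per-repeat confusion summaries.
#' @export
plsda_stability_select <- function(m, labels, params = pls_select_params()) {
  stopifnot(inherits(params, "pls_select_params"))
  m <- drop_qc(m)
  y <- droplevels(factor(labels))
  if (nlevels(y) != 2) abort("labels must have exactly 2 classes")
  if (any(table(y) < 4)) abort("each class needs >= 4 samples")
  X <- canonical_predictors(m)
  if (params$top_k >= ncol(X)) abort("top_k must be below the feature count")
  counts <- stats::setNames(integer(ncol(X)), colnames(X))
  confusions <- vector("list", params$n_repeats)
  for (r in seq_len(params$n_repeats)) {
    with_seed(derive_seed(params$seed, "plsda", r), {
      tr <- stratified_split(y, params$train_frac)
      te <- setdiff(seq_along(y), tr)
      fit <- fit_plsda(X[tr, , drop = FALSE], y[tr],
                       n_components = params$n_components,
                       log_transform = FALSE)
      vip <- vip_scores(fit)
      top <- names(vip)[order(-vip)][seq_len(params$top_k)]
      counts[top] <- counts[top] + 1L
      confusions[[r]] <- list(
        train = confusion_counts(predict(fit, X[tr, , drop = FALSE]), y[tr]),
        test = confusion_counts(predict(fit, X[te, , drop = FALSE]), y[te]))
    })
  }
  # min_freq = 0 degenerates to "every feature ever recorded in a top_k"
  selected <- names(counts)[counts >= max(params$min_freq, 1L)]
  new_selection_result("plsda", counts, selected, params, confusions)
}

#' One elementary Random-Forest importance analysis
#'
#' Grows `n_trees` CART trees, each on a bootstrap sample of the full size
#' with `mtry` candidate variables per split, and returns all variables
#' sorted by mean decrease in Gini impurity.
#'
#' @param m a [labeled_matrix()] (QC rows dropped).
#' @param labels two-level factor over the non-QC samples.
#' @param n_trees,mtry forest size and candidate variables per split.
#' @param seed integer seed.
#' @return data.frame `feature_id`, `importance`, `rank` (sorted, rank 1 =
#'   most important; ties broken by canonical feature order).
#' @export
rf_importance_run <- function(m, labels, n_trees = 1000L, mtry = 20L, seed = 1L) {
  m <- drop_qc(m)
  y <- droplevels(factor(labels))
  if (nlevels(y) != 2) abort("labels must have exactly 2 classes")
  if (length(y) < 8) abort("need >= 8 samples")
  X <- canonical_predictors(m)
  if (mtry > ncol(X)) abort("mtry (%d) exceeds the feature count (%d)",
                            mtry, ncol(X))
  imp <- with_seed(seed, {
    fit <- randomForest::randomForest(x = X, y = y, ntree = n_trees,
                                      mtry = mtry, replace = TRUE,
                                      sampsize = length(y))
    fit$importance[, "MeanDecreaseGini"]
  })
  o <- order(-imp)
  data.frame(feature_id = colnames(X)[o], importance = as.numeric(imp[o]),
             rank = seq_along(o), stringsAsFactors = FALSE)
}

#' Random-Forest top-k recurrence stability selection
#'
#' Repeats the elementary importance analysis `n_iterations` times with
#' fresh random streams, counts how often each variable lands in the top
#' `top_k` importances, and selects variables with count at least
#' `retain_min_count`.
#'
#' @param m a [labeled_matrix()].
#' @param labels two-level factor over the non-QC samples.
#' @param params an [rf_select_params()].
#' @return a `selection_result` with per-feature counts and selected ids.
#' @export
rf_stability_select <- function(m, labels, params = rf_select_params()) {
  stopifnot(inherits(params, "rf_select_params"))
  feature_order <- sort(drop_qc(m)$feature_ids)
  counts <- stats::setNames(integer(length(feature_order)), feature_order)
  for (i in seq_len(params$n_iterations)) {
    run <- rf_importance_run(m, labels, n_trees = params$n_trees,
                             mtry = params$mtry,
                             seed = derive_seed(params$seed, "rf", i))
    top <- run$feature_id[seq_len(min(params$top_k, nrow(run)))]
    counts[top] <- counts[top] + 1L
  }
  selected <- names(counts)[counts >= params$retain_min_count]
  new_selection_result("rf", counts, selected, params)
}

#' Serialize a selection result to JSON (and optionally a TSV count table)
#'
#' @param x a `selection_result`.
#' @param path output JSON path.
#' @param tsv_path optional TSV path for the per-feature frequency table.
#' @return `path`, invisibly.
#' @export
write_selection <- function(x, path, tsv_path = NULL) {
  stopifnot(inherits(x, "selection_result"))
  jsonlite::write_json(list(method = x$method,
                            params = unclass(x$params),
                            counts = as.list(x$counts),
                            selected = x$selected),
                       path, auto_unbox = TRUE, digits = NA)
  if (!is.null(tsv_path)) {
    utils::write.table(data.frame(feature_id = names(x$counts),
                                  count = as.integer(x$counts)),
                       tsv_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
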