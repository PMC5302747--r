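#' Confusion counts and accuracy for predicted vs true classes
#'
#' @param predicted,truth factors over the same samples; `truth` levels
#'   define the table layout, and a predicted label absent from the truth
#'   levels is an error.
#' @return list with `table` (true x predicted counts) and `accuracy`.
#' @export
confusion_counts <- function(predicted, truth) {
  truth <- factor(truth)
  predicted <- as.character(predicted)
  unseen <- setdiff(unique(predicted), levels(truth))
  if (length(unseen))
    abort("predicted label(s) not among true classes: %s",
          paste(unseen, collapse = ", "))
  predicted <- factor(predicted, levels = levels(truth))
  tab <- table(truth = truth, predicted = predicted)
  list(table = tab, accuracy = sum(diag(tab)) / length(truth))
}

#' ROC curve and AUC by threshold sweep
#'
#' Classification rule "score >= threshold is positive" swept over every
#' distinct score; the positive class is the second level of `labels`.  AUC
#' is the trapezoidal area, which with this construction equals the
#' Mann-Whitney concordance probability with ties half-credited.
#'
#' @param scores numeric scores, higher = more positive.
#' @param labels two-level factor (second level = positive).
#' @return a `roc_result`: `thresholds`, `fpr`, `tpr` (each from (0,0) to
#'   (1,1)), `auc`.
#' @export
roc_auc <- function(scores, labels) {
  y <- droplevels(factor(labels))
  if (nlevels(y) != 2) abort("need both classes present")
  pos <- y == levels(y)[2]
  n1 <- sum(pos); n0 <- sum(!pos)
  thr <- sort(unique(scores), decreasing = TRUE)
  tp <- vapply(thr, function(t) sum(scores >= t & pos), numeric(1))
  fp <- vapply(thr, function(t) sum(scores >= t & !pos), numeric(1))
  tpr <- c(0, tp / n1)
  fpr <- c(0, fp / n0)
  auc <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  structure(list(thresholds = c(Inf, thr), fpr = fpr, tpr = tpr, auc = auc),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("roc_result: AUC = %.3f over %d thresholds\n",
              x$auc, length(x$thresholds)))
  invisible(x)
}

# LDA with a ridge fallback for singular within-class covariance.
# Returns an object with a predict(obj, X) -> list(class, score) interface;
# score is the discriminant value oriented so the positive (second) class
# scores higher.
lda_fit <- function(X, y, ridge = 1e-6) {
  X <- as.matrix(X)
  y <- droplevels(factor(y))
  fit <- tryCatch(suppressWarnings(MASS::lda(X, grouping = y)),
                  error = function(e) NULL)
  if (!is.null(fit)) {
    return(structure(list(fit = fit, levels = levels(y), flagged = FALSE),
                     class = "lda_panel_fit"))
  }
  # pooled within-class covariance + ridge
  mu <- lapply(levels(y), function(lv) colMeans(X[y == lv, , drop = FALSE]))
  Sw <- matrix(0, ncol(X), ncol(X))
  for (lv in levels(y)) {
    Xc <- sweep(X[y == lv, , drop = FALSE], 2, colMeans(X[y == lv, , drop = FALSE]))
    Sw <- Sw + crossprod(Xc)
  }
  Sw <- Sw / (nrow(X) - 2) + ridge * mean(diag(Sw) + ridge) * diag(ncol(X))
  w <- solve(Sw, mu[[2]] - mu[[1]])
  cut <- sum(w * (mu[[1]] + mu[[2]])) / 2 -
    log(sum(y == levels(y)[2]) / sum(y == levels(y)[1]))
  structure(list(w = w, cut = cut, levels = levels(y), flagged = TRUE),
            class = "ridge_lda_fit")
}

lda_predict <- function(obj, X) {
  X <- as.matrix(X)
  if (inherits(obj, "lda_panel_fit")) {
    pr <- stats::predict(obj$fit, X)
    score <- pr$posterior[, obj$levels[2]]
    list(class = factor(as.character(pr$class), levels = obj$levels),
         score = as.numeric(score))
  } else {
    s <- drop(X %*% obj$w) - obj$cut
    list(class = factor(obj$levels[(s > 0) + 1L], levels = obj$levels),
         score = s)
  }
}

# deterministic stratified fold assignment (samples of each class dealt
# round-robin to folds in order)
stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (lv in levels(y)) {
    rows <- which(y == lv)
    fold[rows] <- rep(seq_len(k), length.out = length(rows))
  }
  fold
}

cv_accuracy <- function(X, y, vars, folds) {
  k <- max(folds)
  correct <- 0L
  for (f in seq_len(k)) {
    tr <- folds != f
    if (nlevels(droplevels(y[tr])) < 2) return(NA_real_)
    fit <- lda_fit(X[tr, vars, drop = FALSE], y[tr])
    pr <- lda_predict(fit, X[!tr, vars, drop = FALSE])
    correct <- correct + sum(pr$class == y[!tr])
  }
  correct / length(y)
}

#' Forward stepwise LDA maximizing cross-validated accuracy
#'
#' Starting from the empty panel (majority-class rule), repeatedly adds the
#' candidate variable that most improves stratified k-fold cross-validated
#' accuracy, stopping when no candidate improves it by more than
#' `tolerance` (default 1/(2n), half a sample).  Ties go to the candidate
#' earlier in canonical (sorted-id) order.  The final LDA is refit on all
#' data; a singular within-class covariance falls back to a
#' ridge-regularized fit with a warning.
#'
#' @param m a [labeled_matrix()] (QC rows dropped; log scale used).
#' @param labels two-level factor over the non-QC samples.
#' @param candidates feature ids to search over (>= 1).
#' @param cv_folds folds for the stratified CV (default 5).
#' @param tolerance minimum accuracy improvement to accept a variable.
#' @return a `fitted_panel` (method `"lda"`).
#' @export
stepwise_lda <- function(m, labels, candidates, cv_folds = 5L,
                         tolerance = NULL) {
  m <- drop_qc(m)
  y <- droplevels(factor(labels))
  if (nlevels(y) != 2) abort("labels must have exactly 2 classes")
  if (!length(candidates)) abort("need >= 1 candidate")
  missing_f <- setdiff(candidates, m$feature_ids)
  if (length(missing_f))
    abort("candidate(s) absent from the matrix: %s",
          paste(missing_f, collapse = ", "))
  candidates <- sort(candidates)
  X <- log(m$values)
  if (is.null(tolerance)) tolerance <- 1 / (2 * length(y))
  folds <- stratified_folds(y, min(cv_folds, min(table(y))))
  panel <- character(0)
  best_acc <- max(table(y)) / length(y)       # majority baseline
  repeat {
    remaining <- setdiff(candidates, panel)
    if (!length(remaining)) break
    accs <- vapply(remaining, function(v)
      cv_accuracy(X, y, c(panel, v), folds), numeric(1))
    j <- which.max(accs)                       # first max = smaller index
    if (is.na(accs[j]) || accs[j] <= best_acc + tolerance) break
    panel <- c(panel, remaining[j])
    best_acc <- unname(accs[j])
  }
  if (!length(panel)) panel <- candidates[1]   # never return an empty LDA
  fit <- lda_fit(X[, panel, drop = FALSE], y)
  if (fit$flagged)
    warning("singular within-class covariance: ridge-regularized LDA used")
  structure(list(method = "lda", variables = panel, fit = fit,
                 cv_accuracy = best_acc, levels = levels(y),
                 flagged = fit$flagged),
            class = "fitted_panel")
}

# ridge-penalized logistic regression by Newton iterations (separation
# fallback); penalty excluded from the intercept
ridge_logistic <- function(X, y01, lambda = 1) {
  Xd <- cbind(1, as.matrix(X))
  beta <- numeric(ncol(Xd))
  pen <- c(0, rep(lambda, ncol(Xd) - 1))
  for (it in 1:50) {
    eta <- drop(Xd %*% beta)
    p <- 1 / (1 + exp(-eta))
    w <- pmax(p * (1 - p), 1e-8)
    H <- crossprod(Xd, Xd * w) + diag(pen, ncol(Xd))
    g <- crossprod(Xd, y01 - p) - pen * beta
    step <- solve(H, g)
    beta <- beta + step
    if (max(abs(step)) < 1e-8) break
  }
  beta
}

#' Bidirectional stepwise-AIC logistic regression
#'
#' Starting from the intercept-only binomial GLM, a bidirectional stepwise
#' search over the candidate variables minimizes the Akaike information
#' criterion; the AIC-optimal variable set and coefficients form the panel.
#' Perfect separation in the final model triggers a ridge-penalized refit,
#' flagged.
#'
#' @param m a [labeled_matrix()] (QC rows dropped; log scale used).
#' @param labels two-level factor (second level = positive class).
#' @param candidates feature ids to search over; empty gives the
#'   intercept-only model.
#' @return a `fitted_panel` (method `"logistic"`).
#' @export
stepwise_logistic_aic <- function(m, labels, candidates) {
  m <- drop_qc(m)
  y <- droplevels(factor(labels))
  if (nlevels(y) != 2) abort("labels must have exactly 2 classes")
  candidates <- sort(intersect(candidates, m$feature_ids))
  df <- as.data.frame(log(m$values[, candidates, drop = FALSE]))
  safe <- sprintf("x%d", seq_along(candidates))   # syntactic names for formulas
  names(df) <- safe
  df$.y <- as.integer(y == levels(y)[2])
  base <- stats::glm(.y ~ 1, family = stats::binomial(), data = df)
  if (length(candidates)) {
    scope <- stats::as.formula(paste("~", paste(safe, collapse = " + ")))
    sep_flag <- FALSE
    fit <- withCallingHandlers(
      stats::step(base, scope = list(lower = ~1, upper = scope),
                  direction = "both", trace = 0),
      warning = function(w) {
        if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
          sep_flag <<- TRUE
        invokeRestart("muffleWarning")
      })
  } else {
    fit <- base
    sep_flag <- FALSE
  }
  used_safe <- setdiff(names(stats::coef(fit)), "(Intercept)")
  variables <- candidates[match(used_safe, safe)]
  beta <- stats::coef(fit)
  if (sep_flag && length(variables)) {
    rb <- ridge_logistic(df[, used_safe, drop = FALSE], df$.y)
    beta <- stats::setNames(rb, c("(Intercept)", used_safe))
    warning("perfect separation: ridge-penalized logistic fit used")
  }
  structure(list(method = "logistic", variables = variables,
                 coefficients = stats::setNames(
                   beta, c("(Intercept)", variables)[seq_along(beta)]),
                 aic = stats::AIC(fit), levels = levels(y), flagged = sep_flag),
            class = "fitted_panel")
}

#' @export
print.fitted_panel <- function(x, ...) {
  cat(sprintf("fitted_panel (%s): %s\n", x$method,
              if (length(x$variables)) paste(x$variables, collapse = " / ")
              else "<intercept only>"))
  if (!is.null(x$cv_accuracy))
    cat(sprintf("  CV accuracy %.3f\n", x$cv_accuracy))
  if (!is.null(x$aic)) cat(sprintf("  AIC %.2f\n", x$aic))
  invisible(x)
}

#' Discriminant scores and classes of a fitted panel on new data
#'
#' @param object a `fitted_panel`.
#' @param newdata a [labeled_matrix()] containing the panel variables.
#' @param type `"class"` or `"score"` (LDA discriminant value or logistic
#'   linear predictor).
#' @param ... unused.
#' @return factor of classes or numeric scores.
#' @export
predict.fitted_panel <- function(object, newdata, type = c("class", "score"),
                                 ...) {
  type <- match.arg(type)
  stopifnot(inherits(newdata, "labeled_matrix"))
  if (object$method == "logistic" && !length(object$variables)) {
    p0 <- 1 / (1 + exp(-object$coefficients[["(Intercept)"]]))
    score <- rep(p0, nrow(newdata$values))
    cls <- factor(rep(object$levels[(p0 > 0.5) + 1L], length(score)),
                  levels = object$levels)
    return(if (type == "score") score else cls)
  }
  X <- log(newdata$values[, object$variables, drop = FALSE])
  if (object$method == "lda") {
    pr <- lda_predict(object$fit, X)
    if (type == "score") pr$score else pr$class
  } else {
    eta <- drop(cbind(1, X) %*% object$coefficients)
    if (type == "score") eta
    else factor(object$levels[(eta > 0) + 1L], levels = object$levels)
  }
}

#' Confusion matrix of a fitted panel at its default decision rule
#'
#' @param panel a `fitted_panel`.
#' @param m a [labeled_matrix()] with the panel variables.
#' @param labels true classes of the non-QC samples of `m`.
#' @return a [confusion_counts()] summary.
#' @export
confusion_matrix <- function(panel, m, labels) {
  m <- drop_qc(m)
  confusion_counts(predict(panel, m), factor(labels))
}

#' Deterministic PCA scores on a feature subset
#'
#' PCA of centered, unit-variance-scaled log intensities of the selected
#' features; zero-variance features are dropped with a warning; each
#' component's sign is fixed so its largest-magnitude loading is positive.
#'
#' @param m a [labeled_matrix()] (QC rows dropped).
#' @param feature_subset feature ids to project (default: all).
#' @return list with `scores` (samples x components), `explained`
#'   (variance fractions), `loadings`.
#' @export
pca_scores <- function(m, feature_subset = NULL) {
  m <- drop_qc(m)
  if (is.null(feature_subset)) feature_subset <- m$feature_ids
  X <- log(m$values[, feature_subset, drop = FALSE])
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) {
    warning(sum(sds == 0), " zero-variance feature(s) dropped from PCA")
    X <- X[, sds > 0, drop = FALSE]
  }
  if (!ncol(X)) abort("no features with variance for PCA")
  pc <- stats::prcomp(X, center = TRUE, scale. = TRUE)
  for (j in seq_len(ncol(pc$rotation))) {
    i_max <- which.max(abs(pc$rotation[, j]))
    if (pc$rotation[i_max, j] < 0) {
      pc$rotation[, j] <- -pc$rotation[, j]
      pc$x[, j] <- -pc$x[, j]
    }
  }
  list(scores = pc$x, explained = pc$sdev^2 / sum(pc$sdev^2),
       loadings = pc$rotation)
}

# class-wise binned counts along the discriminant axis (the paired-histogram
# view of discrimination quality, exported as data)
score_histogram <- function(scores, labels, n_bins = 10L) {
  breaks <- seq(min(scores), max(scores), length.out = n_bins + 1L)
  if (breaks[1] == breaks[n_bins + 1L]) breaks <- breaks[1] + c(-0.5, 0.5)
  y <- factor(labels)
  out <- lapply(levels(y), function(lv)
    graphics::hist(scores[y == lv], breaks = breaks, plot = FALSE)$counts)
  names(out) <- levels(y)
  list(breaks = breaks, counts = out)
}

#' End-to-end panel evaluation on a train/test split
#'
#' Refines the candidate set into a panel on the training samples (stepwise
#' LDA or stepwise-AIC logistic), then reports learning- and test-sample
#' confusion matrices, ROC curves and AUCs (resubstitution, cross-validated
#' on the training samples, and held-out test — labeled separately), PCA
#' scores of the panel features, and the class histograms along the
#' discriminant axis.  An empty candidate set yields the majority-rule
#' baseline report.
#'
#' @param m_train,m_test [labeled_matrix()] objects on the same feature
#'   space.
#' @param labels_train,labels_test two-level factors for the non-QC rows.
#' @param candidates feature ids entering panel refinement.
#' @param method `"lda"` or `"logistic"`.
#' @param cv_folds folds for the CV AUC (default 5).
#' @return an `eval_report`.
#' @export
evaluate_panel <- function(m_train, m_test, labels_train, labels_test,
                           candidates, method = c("lda", "logistic"),
                           cv_folds = 5L) {
  method <- match.arg(method)
  if (!identical(m_train$feature_ids, m_test$feature_ids))
    abort("train and test matrices have different feature spaces")
  m_train <- drop_qc(m_train); m_test <- drop_qc(m_test)
  y_tr <- droplevels(factor(labels_train))
  y_te <- factor(labels_test, levels = levels(y_tr))

  if (!length(candidates)) {
    maj <- levels(y_tr)[which.max(table(y_tr))]
    pred_te <- factor(rep(maj, length(y_te)), levels = levels(y_tr))
    return(structure(list(panel = NULL, method = "majority-baseline",
                          confusion = list(
                            train = confusion_counts(
                              factor(rep(maj, length(y_tr)), levels(y_tr)), y_tr),
                            test = confusion_counts(pred_te, y_te)),
                          roc = NULL, auc = NULL, pca = NULL, histogram = NULL),
                     class = "eval_report"))
  }

  panel <- if (method == "lda")
    stepwise_lda(m_train, y_tr, candidates, cv_folds = cv_folds)
  else stepwise_logistic_aic(m_train, y_tr, candidates)

  score_tr <- predict(panel, m_train, type = "score")
  score_te <- predict(panel, m_test, type = "score")
  # cross-validated scores on the training samples (panel variables fixed)
  folds <- stratified_folds(y_tr, min(cv_folds, min(table(y_tr))))
  score_cv <- rep(NA_real_, length(y_tr))
  vars <- if (length(panel$variables)) panel$variables else candidates[1]
  Xtr <- log(m_train$values[, vars, drop = FALSE])
  for (f in seq_len(max(folds))) {
    tr <- folds != f
    fit_f <- lda_fit(Xtr[tr, , drop = FALSE], y_tr[tr])
    score_cv[!tr] <- lda_predict(fit_f, Xtr[!tr, , drop = FALSE])$score
  }

  roc_tr <- roc_auc(score_tr, y_tr)
  roc_cv <- roc_auc(score_cv, y_tr)
  roc_te <- roc_auc(score_te, y_te)
  structure(list(
    panel = panel, method = method,
    confusion = list(train = confusion_counts(predict(panel, m_train), y_tr),
                     test = confusion_counts(predict(panel, m_test), y_te)),
    roc = list(resubstitution = roc_tr, cv = roc_cv, test = roc_te),
    auc = c(resubstitution = roc_tr$auc, cv = roc_cv$auc, test = roc_te$auc),
    pca = pca_scores(m_train, vars),
    histogram = score_histogram(score_te, y_te)),
    class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("eval_report (%s)\n", x$method))
  if (!is.null(x$panel))
    cat(sprintf("  panel: %s\n", paste(x$panel$variables, collapse = " / ")))
  cat(sprintf("  accuracy: train %.3f, test %.3f\n",
              x$confusion$train$accuracy, x$confusion$test$accuracy))
  if (!is.null(x$auc))
    cat(sprintf("  AUC: resubstitution %.3f, CV %.3f, test %.3f\n",
                x$auc["resubstitution"], x$auc["cv"], x$auc["test"]))
  invisible(x)
}

#' Serialize an evaluation report to JSON (+ optional TSVs)
#'
#' @param x an `eval_report`.
#' @param path output JSON path.
#' @param roc_tsv,pca_tsv optional TSV paths for the test ROC points and
#'   the PCA scores.
#' @return `path`, invisibly.
#' @export
write_eval_report <- function(x, path, roc_tsv = NULL, pca_tsv = NULL) {
  stopifnot(inherits(x, "eval_report"))
  jsonlite::write_json(list(
    method = x$method,
    panel = if (!is.null(x$panel)) x$panel$variables,
    accuracy = list(train = x$confusion$train$accuracy,
                    test = x$confusion$test$accuracy),
    confusion_test = as.data.frame(x$confusion$test$table),
    auc = if (!is.null(x$auc)) as.list(x$auc),
    histogram = x$histogram),
    path, auto_unbox = TRUE, digits = NA)
  if (!is.null(roc_tsv) && !is.null(x$roc))
    utils::write.table(data.frame(fpr = x$roc$test$fpr, tpr = x$roc$test$tpr),
                       roc_tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(pca_tsv) && !is.null(x$pca))
    utils::write.table(cbind(sample = rownames(x$pca$scores),
                             as.data.frame(x$pca$scores)),
                       pca_tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
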