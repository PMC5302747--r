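#' Fit a two-class PLS-DA model (NIPALS PLS1)
#'
#' Partial least squares regression of a +/-1-coded class membership on
#' centered, unit-variance-scaled predictors ("centered and reduced"),
#' used as a classifier.  The fit is the deterministic NIPALS sequence for a
#' univariate response: for each component, the weight vector is the
#' covariance direction X'y (normalised), followed by score, loading and
#' deflation steps.  Zero-variance columns are dropped with a warning.
#'
#' @param X numeric matrix, samples x variables (or a [labeled_matrix()]).
#' @param y two-level factor (or vector coercible to one); both classes must
#'   be present.
#' @param n_components number of latent components (default 2; at most
#'   rank-limited by min(n - 1, p)).
#' @param log_transform when `X` is a [labeled_matrix()], log the
#'   intensities first (default TRUE).
#' @return an object of class `plsda`: weights `W`, x-loadings `P`,
#'   y-loadings `q`, scores `T`, per-component explained y-variance `ssy`,
#'   centering/scaling vectors, class levels.
#' @export
fit_plsda <- function(X, y, n_components = 2L, log_transform = TRUE) {
  if (inherits(X, "labeled_matrix")) {
    X <- if (log_transform) log(X$values) else X$values
  }
  X <- as.matrix(X)
  y <- factor(y)
  if (nlevels(y) != 2) abort("y must have exactly 2 classes (got %d)", nlevels(y))
  if (any(table(y) < 2)) abort("each class needs >= 2 samples")
  if (nrow(X) != length(y)) abort("X rows and y length differ")
  yn <- ifelse(y == levels(y)[2], 1, -1)

  x_mean <- colMeans(X)
  x_sd <- apply(X, 2, stats::sd)
  keep <- x_sd > 0
  if (!all(keep)) {
    warning(sum(!keep), " zero-variance column(s) dropped")
    X <- X[, keep, drop = FALSE]
    x_mean <- x_mean[keep]; x_sd <- x_sd[keep]
  }
  if (!ncol(X)) abort("no variables left after dropping zero-variance columns")
  Xc <- sweep(sweep(X, 2, x_mean), 2, x_sd, "/")
  y_mean <- mean(yn)
  yc <- yn - y_mean

  a_max <- min(n_components, nrow(Xc) - 1L, ncol(Xc))
  p <- ncol(Xc)
  W <- P <- matrix(0, p, a_max)
  Tm <- matrix(0, nrow(Xc), a_max)
  q <- numeric(a_max)
  ssy <- numeric(a_max)
  Xa <- Xc; ya <- yc
  for (a in seq_len(a_max)) {
    w <- drop(crossprod(Xa, ya))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) { a_max <- a - 1L; break }
    w <- w / nw
    tt <- drop(Xa %*% w)
    tt2 <- sum(tt^2)
    pl <- drop(crossprod(Xa, tt)) / tt2
    qa <- sum(ya * tt) / tt2
    Xa <- Xa - tcrossprod(tt, pl)
    ya <- ya - qa * tt
    W[, a] <- w; P[, a] <- pl; Tm[, a] <- tt
    q[a] <- qa; ssy[a] <- qa^2 * tt2
  }
  if (a_max < 1) abort("no informative component could be extracted")
  idx <- seq_len(a_max)
  structure(list(W = W[, idx, drop = FALSE], P = P[, idx, drop = FALSE],
                 scores = Tm[, idx, drop = FALSE], q = q[idx], ssy = ssy[idx],
                 sst_y = sum(yc^2), x_mean = x_mean, x_sd = x_sd,
                 y_mean = y_mean, levels = levels(y),
                 var_names = colnames(X) %||% sprintf("V%d", seq_len(p)),
                 n_components = a_max),
            class = "plsda")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.plsda <- function(x, ...) {
  cat(sprintf("plsda: %d component(s), %d variables, classes %s vs %s\n",
              x$n_components, nrow(x$W), x$levels[1], x$levels[2]))
  cat(sprintf("  explained y-variance per component: %s\n",
              paste(sprintf("%.1f%%", 100 * x$ssy / x$sst_y), collapse = ", ")))
  invisible(x)
}

#' Regression coefficients of a fitted PLS-DA model (scaled-X basis)
#' @param object a `plsda` fit.
#' @param ... unused.
#' @return named coefficient vector b with yhat = y_mean + Xs b.
#' @export
coef.plsda <- function(object, ...) {
  b <- drop(object$W %*% solve(crossprod(object$P, object$W), object$q))
  names(b) <- object$var_names
  b
}

#' Predict class or discriminant score from a PLS-DA fit
#'
#' @param object a `plsda` fit.
#' @param newdata matrix with the same variables as the training data.
#' @param type `"class"` (default) or `"score"` (the continuous
#'   discriminant value; positive values favour the second class level).
#' @param ... unused.
#' @return factor of classes, or numeric scores.
#' @export
predict.plsda <- function(object, newdata, type = c("class", "score"), ...) {
  type <- match.arg(type)
  newdata <- as.matrix(newdata)
  Xs <- sweep(sweep(newdata, 2, object$x_mean), 2, object$x_sd, "/")
  score <- object$y_mean + drop(Xs %*% coef(object))
  if (type == "score") return(score)
  factor(object$levels[(score > 0) + 1L], levels = object$levels)
}

#' Variable importance in projection (VIP)
#'
#' VIP_j = sqrt( p * sum_a SSY_a (w_aj / ||w_a||)^2 / sum_a SSY_a ), where
#' SSY_a is the y-variance explained by component a and w_a its weight
#' vector.  The mean squared VIP is 1 by construction, so variables with
#' VIP > 1 are more important than average.
#'
#' @param model a fitted `plsda`.
#' @return named numeric vector of VIP scores (sums of squares equal p).
#' @export
vip_scores <- function(model) {
  stopifnot(inherits(model, "plsda"))
  W <- model$W
  wn2 <- sweep(W^2, 2, colSums(W^2), "/")     # (w_aj/||w_a||)^2
  p <- nrow(W)
  v <- sqrt(p * drop(wn2 %*% model$ssy) / sum(model$ssy))
  names(v) <- model$var_names
  v
}
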