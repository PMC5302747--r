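# pairwise-concordance AUC oracle: P(score_pos > score_neg) + 0.5 P(tie)
auc_by_pairs <- function(scores, labels) {
  y <- factor(labels)
  pos <- scores[y == levels(y)[2]]
  neg <- scores[y == levels(y)[1]]
  pairs <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(pairs)
}

test_that("ROC/AUC reproduces the closed-form cases", {
  lab <- factor(c("pos", "pos", "neg", "neg"), levels = c("neg", "pos"))
  expect_equal(roc_auc(c(0.9, 0.8, 0.1, 0.2), lab)$auc, 1.0)
  expect_equal(roc_auc(rep(0.5, 4), lab)$auc, 0.5)
  expect_equal(roc_auc(c(0.9, 0.3, 0.5, 0.1), lab)$auc, 0.75)
  expect_error(roc_auc(1:3, factor(rep("a", 3))), "both classes")
})

test_that("trapezoid AUC equals pair concordance on random instances", {
  set.seed(13)
  for (i in 1:100) {
    n <- sample(4:50, 1)
    y <- factor(sample(c("a", "b"), n, replace = TRUE), levels = c("a", "b"))
    y[1:2] <- c("a", "b")
    s <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)   # forces ties
    expect_equal(roc_auc(s, y)$auc, auc_by_pairs(s, y), tolerance = 1e-12)
  }
})

test_that("ROC endpoints, monotonicity, and score-negation symmetry hold", {
  set.seed(14)
  y <- factor(sample(c("a", "b"), 30, replace = TRUE), levels = c("a", "b"))
  y[1:2] <- c("a", "b")
  s <- rnorm(30)
  r <- roc_auc(s, y)
  expect_equal(c(r$fpr[1], r$tpr[1]), c(0, 0))
  expect_equal(c(r$fpr[length(r$fpr)], r$tpr[length(r$tpr)]), c(1, 1))
  expect_true(all(diff(r$fpr) >= 0) && all(diff(r$tpr) >= 0))
  expect_equal(r$auc, 1 - roc_auc(-s, y)$auc, tolerance = 1e-12)
})

test_that("AUC agrees with the pROC reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(15)
  y <- factor(rep(c("a", "b"), each = 20))
  s <- rnorm(40) + ifelse(y == "b", 1, 0)
  ref <- as.numeric(suppressMessages(
    pROC::auc(pROC::roc(y, s, levels = c("a", "b"), direction = "<"))))
  expect_equal(roc_auc(s, y)$auc, ref, tolerance = 1e-12)
})

test_that("stepwise LDA picks a perfect separator and resists pure noise", {
  set.seed(16)
  n <- 32
  vals <- matrix(exp(rnorm(n * 10)), n, 10)
  vals[, 4] <- exp(c(rnorm(n / 2, -4, 0.3), rnorm(n / 2, 4, 0.3)))
  m <- lm_from_values(vals, doses = rep(c(0, 20), each = n / 2))
  y <- factor(rep(c("ctrl", "ir"), each = n / 2))
  panel <- stepwise_lda(m, y, m$feature_ids)
  expect_true("f004" %in% panel$variables)
  expect_equal(panel$cv_accuracy, 1.0)

  # all-noise candidates: the stepwise CV estimate is optimistically biased
  # (it maximizes over candidates), but accuracy on an independent test set
  # must sit at the majority-class rate
  null_acc <- vapply(1:10, function(s) {
    set.seed(100 + s)
    vn <- matrix(exp(rnorm(2 * n * 8)), 2 * n, 8)
    mn <- lm_from_values(vn, doses = rep(rep(c(0, 20), each = n / 2), 2))
    panel <- stepwise_lda(lm_subset(mn, 1:n), y, mn$feature_ids)
    mean(predict(panel, lm_subset(mn, n + 1:n)) == y)
  }, numeric(1))
  mc_se <- sd(null_acc) / sqrt(10)
  expect_lt(abs(mean(null_acc) - 0.5), max(2 * mc_se, 0.1))
})

test_that("a redundant copy of an informative variable does not enter twice", {
  set.seed(18)
  n <- 40
  base <- c(rnorm(n / 2, -2, 0.5), rnorm(n / 2, 2, 0.5))
  vals <- cbind(exp(base), exp(base + rnorm(n, 0, 0.01)),
                matrix(exp(rnorm(n * 4)), n, 4))
  m <- lm_from_values(vals, doses = rep(c(0, 20), each = n / 2))
  y <- factor(rep(c("a", "b"), each = n / 2))
  panel <- stepwise_lda(m, y, m$feature_ids)
  expect_equal(sum(c("f001", "f002") %in% panel$variables), 1L)
})

test_that("LDA on one variable is the closed-form two-Gaussian threshold rule", {
  set.seed(19)
  n <- 30
  x <- c(rnorm(n / 2, 0, 1), rnorm(n / 2, 2, 1))
  m <- lm_from_values(matrix(exp(x), ncol = 1),
                      doses = rep(c(0, 20), each = n / 2))
  y <- factor(rep(c("a", "b"), each = n / 2))
  panel <- stepwise_lda(m, y, "f001")
  pred <- predict(panel, m)
  # equal-covariance rule: classify "b" when x is beyond the midpoint
  # adjusted by the pooled-variance log-prior term (priors equal here)
  mu <- tapply(x, y, mean)
  thr <- mean(mu)
  expect_equal(as.character(pred), ifelse(x > thr, "b", "a"))
})

test_that("stepwise-AIC logistic keeps strong predictors, rejects pure noise", {
  set.seed(20)
  n <- 64
  lab <- factor(rep(c("a", "b"), each = n / 2))
  # single null candidate: the stepwise decision must coincide with the
  # direct AIC comparison of the one-variable fit against intercept-only
  for (s in 1:8) {
    set.seed(300 + s)
    vn <- matrix(exp(rnorm(n)), n, 1)
    mn <- lm_from_values(vn, doses = rep(c(0, 20), each = n / 2))
    fit1 <- glm(I(lab == "b") ~ log(vn[, 1]), family = binomial())
    fit0 <- glm(I(lab == "b") ~ 1, family = binomial())
    kept <- length(stepwise_logistic_aic(mn, lab, "f001")$variables) == 1
    expect_equal(kept, AIC(fit1) < AIC(fit0))
  }
  # with several null candidates the panel never grows beyond chance size
  sizes <- vapply(1:8, function(s) {
    set.seed(400 + s)
    vn <- matrix(exp(rnorm(n * 6)), n, 6)
    mn <- lm_from_values(vn, doses = rep(c(0, 20), each = n / 2))
    length(stepwise_logistic_aic(mn, lab, mn$feature_ids)$variables)
  }, integer(1))
  expect_lt(mean(sizes), 2)

  vals <- matrix(exp(rnorm(n * 6)), n, 6)
  vals[, 2] <- vals[, 2] * ifelse(lab == "b", 2, 1)      # fold-2 predictor
  ms <- lm_from_values(vals, doses = rep(c(0, 20), each = n / 2))
  panel <- stepwise_logistic_aic(ms, lab, ms$feature_ids)
  expect_true("f002" %in% panel$variables)
  null_fit <- glm(I(lab == "b") ~ 1, family = binomial())
  expect_lt(panel$aic, AIC(null_fit))

  empty <- stepwise_logistic_aic(ms, lab, character(0))
  expect_length(empty$variables, 0L)
})

test_that("confusion matrices conserve counts and detect label problems", {
  y <- factor(c("a", "a", "b", "b"))
  perfect <- confusion_counts(y, y)
  expect_equal(sum(perfect$table), 4)
  expect_equal(perfect$table["a", "b"] + perfect$table["b", "a"], 0)
  expect_equal(perfect$accuracy, 1)
  constant <- confusion_counts(factor(rep("a", 4), levels(y)), y)
  expect_equal(sum(constant$table[, "b"]), 0)
  expect_error(confusion_counts(factor(c("a", "c", "b", "b")), y), "c")
})

test_that("PCA scores are centered, sign-fixed, and catch collinearity", {
  set.seed(22)
  base <- rnorm(20)
  vals <- exp(cbind(base, 2 * base + 3, rnorm(20)))
  m <- lm_from_values(vals)
  out <- pca_scores(m, c("f001", "f002"))
  expect_equal(out$explained[1], 1, tolerance = 1e-10)  # perfectly correlated
  expect_equal(unname(colMeans(out$scores)), rep(0, 2), tolerance = 1e-12)
  # sign convention: the largest-|loading| entry of each component positive
  for (j in seq_len(ncol(out$loadings)))
    expect_gt(out$loadings[which.max(abs(out$loadings[, j])), j], 0)
  vals0 <- cbind(vals, 1)
  m0 <- lm_from_values(vals0)
  expect_warning(pca_scores(m0), "zero-variance")
})

test_that("separated groups stand apart on the PC1-PC2 plane", {
  hits <- 0L
  for (s in 1:10) {
    cfg <- tiny_dige(n_features = 10, seed = 700 + s, batch_sd = 0,
                     markers = list(marker_spec(1, "exposure", 2.5),
                                    marker_spec(2, "exposure", 2.5),
                                    marker_spec(3, "exposure", 0.4)))
    m <- generate_dige_dataset(cfg, 3)
    grp <- m$meta$dose_gy > 0
    sc <- pca_scores(m, c("spot_0001", "spot_0002", "spot_0003"))$scores[, 1:2]
    # silhouette-style score: between-group vs within-group mean distance
    d <- as.matrix(dist(sc))
    within <- mean(d[grp, grp][upper.tri(d[grp, grp])])
    between <- mean(d[grp, !grp])
    hits <- hits + ((between - within) / max(between, within) > 0.3)
  }
  expect_gte(hits, 9L)
})

test_that("panel evaluation separates planted markers and honours baselines", {
  cfg <- tiny_dige(n_features = 80, seed = 30, batch_sd = 0.1,
                   markers = lapply(1:5, function(i)
                     marker_spec(i, "exposure", 1.8)))
  m <- generate_dige_dataset(cfg, 3)
  y <- factor(ifelse(m$meta$dose_gy > 0, "ir", "ctrl"), c("ctrl", "ir"))
  set.seed(31)
  tr <- sort(c(sample(which(y == "ctrl"), 11), sample(which(y == "ir"), 34)))
  te <- setdiff(seq_along(y), tr)
  rep <- evaluate_panel(lm_subset(m, tr), lm_subset(m, te), y[tr], y[te],
                        sprintf("spot_%04d", 1:5), method = "lda")
  expect_gte(rep$auc[["test"]], 0.85)
  expect_named(rep$auc, c("resubstitution", "cv", "test"))
  expect_equal(sum(rep$confusion$test$table), length(te))
  expect_equal(sum(unlist(rep$histogram$counts)), length(te))

  base <- evaluate_panel(lm_subset(m, tr), lm_subset(m, te), y[tr], y[te],
                         character(0), method = "lda")
  expect_equal(base$method, "majority-baseline")
  expect_equal(base$confusion$test$accuracy, mean(y[te] == "ir"))
})

test_that("training accuracy dominates test accuracy on average", {
  gaps <- vapply(1:12, function(s) {
    cfg <- tiny_dige(n_features = 60, seed = 800 + s, batch_sd = 0,
                     markers = list(marker_spec(1, "exposure", 1.4)))
    m <- generate_dige_dataset(cfg, 3)
    y <- factor(ifelse(m$meta$dose_gy > 0, "ir", "ctrl"), c("ctrl", "ir"))
    set.seed(s)
    tr <- sort(c(sample(which(y == "ctrl"), 11), sample(which(y == "ir"), 34)))
    te <- setdiff(seq_along(y), tr)
    rep <- evaluate_panel(lm_subset(m, tr), lm_subset(m, te), y[tr], y[te],
                          m$feature_ids[1:10], method = "lda")
    rep$confusion$train$accuracy - rep$confusion$test$accuracy
  }, numeric(1))
  expect_gte(mean(gaps), 0)
})
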