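# exhaustive two-group permutation oracle: all label assignments of the
# pooled sample, add-one Monte-Carlo convention excluded (exact enumeration)
exact_perm_p <- function(x_left, x_right) {
  pooled <- c(x_left, x_right)
  n_l <- length(x_left)
  obs <- abs(mean(x_left) - mean(x_right))
  picks <- utils::combn(length(pooled), n_l)
  stats <- apply(picks, 2, function(i)
    abs(mean(pooled[i]) - mean(pooled[-i])))
  mean(stats >= obs - 1e-12)
}

test_that("per-feature ANOVA matches the hand-worked F and aov on small data", {
  m <- lm_from_values(matrix(c(1, 2, 3, 2, 3, 4), ncol = 1),
                      doses = c(0, 0, 0, 20, 20, 20))
  out <- anova_per_feature(m, log_transform = FALSE)
  expect_equal(out$statistic, 1.5)
  expect_equal(out$p, 0.2878641, tolerance = 1e-6)

  # cross-check the vectorised path against stats::aov on random data
  set.seed(42)
  vals <- matrix(exp(rnorm(24 * 5)), 24, 5)
  g <- factor(rep(1:3, each = 8))
  m2 <- lm_from_values(vals, doses = rep(c(0, 20, 40), each = 8))
  out2 <- anova_per_feature(m2, g)
  for (j in 1:5) {
    p_aov <- summary(aov(log(vals[, j]) ~ g))[[1]]$`Pr(>F)`[1]
    expect_equal(out2$p[j], p_aov, tolerance = 1e-10)
  }
})

test_that("ANOVA flags fully degenerate features instead of dividing by zero", {
  m <- lm_from_values(matrix(5, 8, 2), doses = rep(c(0, 20), each = 4))
  out <- anova_per_feature(m, log_transform = FALSE)
  expect_true(all(out$degenerate))
  expect_equal(out$p, c(1, 1))
})

test_that("signed fold change uses the symmetric +r / -1/r convention", {
  vals <- cbind(c(4, 4, 2, 2), c(2, 2, 4, 4), c(3, 3, 3, 3))
  m <- lm_from_values(vals, doses = c(20, 20, 0, 0))
  comp <- comparison("ir_vs_ctrl", cells(20, 3), cells(0, 3))
  fc <- fold_change_signed(m, comp)
  expect_equal(fc$fold_change, c(2, -2, 1))
  expect_equal(format_fold(fc$fold_change), c("+2.0", "-2.0", "="))
})

test_that("permutation p-values match exhaustive enumeration on tiny samples", {
  comp <- comparison("ab", cells(20, 3), cells(0, 3))
  set.seed(7)
  for (case in 1:4) {
    x <- exp(rnorm(8, sd = 1))
    m <- lm_from_values(matrix(x, ncol = 1), doses = rep(c(20, 0), each = 4))
    p_exact <- exact_perm_p(log(x[1:4]), log(x[5:8]))
    n_perm <- 4999
    p_mc <- permutation_test(m, comp, n_perm = n_perm, seed = case)$p
    mc_se <- sqrt(p_exact * (1 - p_exact) / n_perm)
    expect_lt(abs(p_mc - p_exact), 3 * mc_se + 2 / n_perm)
  }
})

test_that("permutation p-values follow the add-one Monte-Carlo convention", {
  # a huge separation: no permutation ties or beats the observed statistic,
  # so p must be exactly (0 + 1) / (B + 1)
  vals <- matrix(exp(c(rep(5, 4), rep(0, 4))), ncol = 1)
  m <- lm_from_values(vals + 0.01 * (1:8), doses = rep(c(20, 0), each = 4))
  out <- permutation_test(m, comparison("s", cells(20, 3), cells(0, 3)),
                          n_perm = 99, seed = 1)
  expect_equal(out$p, 1 / 100)
})

test_that("null permutation p-values are near-uniform", {
  set.seed(11)
  vals <- matrix(exp(rnorm(16 * 400)), 16, 400)
  m <- lm_from_values(vals, doses = rep(c(0, 20), each = 8))
  p <- permutation_test(m, comparison("n", cells(20, 3), cells(0, 3)),
                        n_perm = 399, seed = 5)$p
  ks <- suppressWarnings(ks.test(p, "punif"))
  expect_lt(unname(ks$statistic), 0.07)
})

test_that("Benjamini-Yekutieli adjustment reproduces the hand computation", {
  # m = 3, c(3) = 11/6: q = (0.055, 0.055, 0.0733...)
  q <- by_adjust(c(0.01, 0.02, 0.04))
  expect_equal(q, c(0.055, 0.055, 0.0733333333), tolerance = 1e-8)
  # independent step-up oracle, coded from the definition
  by_oracle <- function(p) {
    m <- length(p)
    cm <- sum(1 / seq_len(m))
    o <- order(p)
    q_sorted <- pmin(1, m * cm * p[o] / seq_len(m))
    q_sorted <- rev(cummin(rev(q_sorted)))
    q <- numeric(m); q[o] <- q_sorted; q
  }
  set.seed(3)
  for (i in 1:5) {
    p <- runif(50)
    expect_equal(by_adjust(p), by_oracle(p), tolerance = 1e-12)
  }
  expect_equal(by_adjust(0.03), 0.03)        # c(1) = 1
  expect_equal(by_adjust(rep(1, 5)), rep(1, 5))
})

test_that("BY q-values are monotone in p and never below p", {
  set.seed(9)
  p <- runif(200)
  q <- by_adjust(p)
  expect_true(all(q >= p - 1e-12))
  o <- order(p)
  expect_true(all(diff(q[o]) >= -1e-12))
})

test_that("candidate selection takes the union of per-comparison ANOVA hits", {
  set.seed(21)
  cfg <- tiny_dige(n_features = 60, seed = 21, batch_sd = 0,
                   markers = list(marker_spec(3, "exposure", 2.5),
                                  marker_spec(7, "dose_monotone", 1.8)))
  m <- generate_dige_dataset(cfg, 3)
  comps <- list(comp_ni_ir_d3(),
                comparison("20_vs_80_d3", cells(80, 3), cells(20, 3)))
  st <- run_univariate(m, comps, n_perm = 199, seed = 2)
  sel <- select_candidates(st, alpha = 0.05)
  manual <- unique(c(st[[1]]$feature_id[st[[1]]$p_anova < 0.05],
                     st[[2]]$feature_id[st[[2]]$p_anova < 0.05]))
  expect_setequal(sel$selected, manual)
  expect_equal(sel$union_size, length(manual))
  expect_true(all(c("spot_0003", "spot_0007") %in% sel$selected))
  sel0 <- suppressWarnings(select_candidates(st, alpha = 0))
  expect_length(sel0$selected, 0)
})

test_that("stats tables satisfy their row contracts", {
  cfg <- tiny_dige(n_features = 30, seed = 5)
  m <- generate_dige_dataset(cfg, 3)
  st <- run_univariate(m, list(comp_ni_ir_d3()), n_perm = 99, seed = 1)
  tb <- st[[1]]
  expect_true(all(tb$p_anova >= 0 & tb$p_anova <= 1))
  expect_true(all(tb$q_by >= tb$p_perm))
  expect_true(all(abs(tb$fold_change) >= 1))
})
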