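#' Declare a two-sided group comparison over design cells
#'
#' A comparison names two disjoint sets of (dose, day) design cells, e.g.
#' sham-irradiated versus all irradiated samples at day 3, or 20 Gy versus
#' the pooled 40+80 Gy groups.  Samples are matched by their metadata;
#' QC-pool rows never enter a comparison.
#'
#' @param name label for the comparison.
#' @param left,right data.frames with columns `dose_gy` and `day` listing the
#'   design cells of each side (see [cells()]).
#' @return a `comparison` object.
#' @export
comparison <- function(name, left, right) {
  for (side in list(left, right)) {
    if (!all(c("dose_gy", "day") %in% names(side)) || !nrow(side))
      abort("comparison sides must be non-empty data.frames with dose_gy and day")
  }
  key <- function(s) paste(s$dose_gy, s$day)
  if (length(intersect(key(left), key(right))))
    abort("comparison '%s': sides share design cells", name)
  structure(list(name = name, left = left, right = right), class = "comparison")
}

#' Expand doses and days into a set of design cells
#' @param doses dose levels (Gy).
#' @param days sampling days.
#' @return data.frame of all (dose_gy, day) combinations.
#' @export
cells <- function(doses, days) {
  expand.grid(dose_gy = doses, day = days, KEEP.OUT.ATTRS = FALSE)
}

# row indices of each comparison side within a labeled matrix (QC excluded)
comparison_rows <- function(m, comp) {
  key <- paste(m$meta$dose_gy, m$meta$day)
  ok <- !m$meta$is_qc_pool
  list(left = which(ok & key %in% paste(comp$left$dose_gy, comp$left$day)),
       right = which(ok & key %in% paste(comp$right$dose_gy, comp$right$day)))
}

#' Per-feature one-way fixed-effects ANOVA
#'
#' Vectorised F-test across all features of a log-transformed intensity
#' matrix.  Features with zero within-group variance and equal group means
#' (no information either way) get p = 1 and a degeneracy flag.
#'
#' @param m a [labeled_matrix()] (QC rows are dropped).
#' @param grouping factor over the non-QC samples (>= 2 levels, >= 2 samples
#'   per level).  Defaults to the dose group.
#' @param log_transform log the intensities first (default TRUE; spot
#'   volumes and peak intensities are log-normal).
#' @return data.frame with `feature_id`, `statistic` (F), `p`, `degenerate`.
#' @export
anova_per_feature <- function(m, grouping = NULL, log_transform = TRUE) {
  stopifnot(inherits(m, "labeled_matrix"))
  m <- drop_qc(m)
  if (is.null(grouping)) grouping <- factor(m$meta$dose_gy)
  grouping <- droplevels(factor(grouping))
  if (nlevels(grouping) < 2) abort("need >= 2 groups")
  if (any(table(grouping) < 2)) abort("need >= 2 samples per group")
  X <- m$values
  if (log_transform) {
    if (any(X <= 0)) abort("log transform requires positive intensities")
    X <- log(X)
  }
  n <- nrow(X)
  k <- nlevels(grouping)
  G <- stats::model.matrix(~ grouping - 1)          # n x k indicator
  ng <- colSums(G)
  gm <- sweep(crossprod(G, X), 1, ng, "/")          # k x p group means
  grand <- colMeans(X)
  ssb <- colSums(ng * sweep(gm, 2, grand)^2)
  sst <- colSums(sweep(X, 2, grand)^2)
  ssw <- pmax(0, sst - ssb)
  df1 <- k - 1
  df2 <- n - k
  degenerate <- ssw < 1e-12 & ssb < 1e-12
  f <- ifelse(ssw < 1e-12, ifelse(ssb < 1e-12, 0, Inf), (ssb / df1) / (ssw / df2))
  p <- ifelse(degenerate, 1, stats::pf(f, df1, df2, lower.tail = FALSE))
  data.frame(feature_id = m$feature_ids, statistic = as.numeric(f),
             p = as.numeric(p), degenerate = degenerate,
             stringsAsFactors = FALSE)
}

#' Signed linear-scale fold change between two groups
#'
#' The ratio r of linear-scale group means (left over right), reported with
#' the symmetric sign convention used for spot tables: +r when r >= 1,
#' -1/r when r < 1, so +2 and -2 are equal-magnitude two-fold changes and
#' no change is +1 (displayed "=").
#'
#' @param m a [labeled_matrix()].
#' @param comp a [comparison()]; its left side is the "treated" numerator.
#' @return data.frame with `feature_id`, `fold_change` (signed),
#'   `mean_left`, `mean_right`.
#' @export
fold_change_signed <- function(m, comp) {
  idx <- comparison_rows(m, comp)
  if (!length(idx$left) || !length(idx$right))
    abort("comparison '%s': empty side", comp$name)
  ml <- colMeans(m$values[idx$left, , drop = FALSE])
  mr <- colMeans(m$values[idx$right, , drop = FALSE])
  if (any(ml <= 0) || any(mr <= 0)) abort("non-positive group mean")
  r <- ml / mr
  fc <- ifelse(r >= 1, r, -1 / r)
  data.frame(feature_id = m$feature_ids, fold_change = fc,
             mean_left = ml, mean_right = mr, stringsAsFactors = FALSE)
}

#' Format signed fold changes as in spot tables
#' @param fc signed fold changes from [fold_change_signed()].
#' @return character vector, `"="` where the fold change is exactly 1.
#' @export
format_fold <- function(fc) ifelse(fc == 1, "=", sprintf("%+.1f", fc))

#' Monte-Carlo permutation test of a two-group mean difference
#'
#' Per-feature statistic |difference of log-scale group means|; group labels
#' are permuted jointly across all features, preserving the between-feature
#' correlation structure.  p = (b + 1) / (B + 1) where b counts permutations
#' with a statistic at least as large as observed — the add-one Monte-Carlo
#' estimate of the exact permutation probability.
#'
#' @param m a [labeled_matrix()].
#' @param comp a [comparison()].
#' @param n_perm number of random permutations B (>= 99; default 9999).
#' @param seed integer seed for the permutation stream.
#' @param log_transform log intensities first (default TRUE).
#' @return data.frame with `feature_id`, `statistic`, `p`.
#' @export
permutation_test <- function(m, comp, n_perm = 9999L, seed = 1L,
                             log_transform = TRUE) {
  if (n_perm < 99) abort("n_perm must be >= 99")
  idx <- comparison_rows(m, comp)
  n_l <- length(idx$left); n_r <- length(idx$right)
  if (n_l < 2 || n_r < 2) abort("each side needs >= 2 samples")
  X <- m$values[c(idx$left, idx$right), , drop = FALSE]
  if (log_transform) X <- log(X)
  n <- n_l + n_r
  w_obs <- c(rep(1 / n_l, n_l), rep(-1 / n_r, n_r))
  obs <- abs(drop(crossprod(X, w_obs)))
  count <- numeric(ncol(X))
  # ties between permuted and observed statistics are exact in theory but
  # only near-exact in floating point; compare with a relative tolerance so
  # tied permutations count as "at least as extreme"
  obs_tol <- obs * (1 - 1e-9) - 1e-300
  with_seed(derive_seed(seed, "perm", comp$name), {
    block <- 500L
    done <- 0L
    while (done < n_perm) {
      b <- min(block, n_perm - done)
      W <- vapply(seq_len(b), function(i) w_obs[sample.int(n)], numeric(n))
      stat <- abs(crossprod(X, W))               # p x b
      count <- count + rowSums(stat >= obs_tol)
      done <- done + b
    }
  })
  data.frame(feature_id = m$feature_ids, statistic = obs,
             p = (count + 1) / (n_perm + 1), stringsAsFactors = FALSE)
}

#' Benjamini-Yekutieli FDR adjustment
#'
#' Step-up FDR control valid under arbitrary dependence between tests, using
#' the harmonic-sum inflation c(m) = sum(1/k).  Applied over the totality of
#' the features of a comparison, not only pre-selected ones.
#'
#' @param p vector of p-values in `[0, 1]`.
#' @return adjusted q-values (same length and order).
#' @export
by_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) abort("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BY")
}

#' Run the univariate battery over a set of comparisons
#'
#' For every comparison: two-group ANOVA p-value, signed fold change,
#' Monte-Carlo permutation p-value, and Benjamini-Yekutieli q-value over all
#' features.
#'
#' @param m a [labeled_matrix()].
#' @param comparisons list of [comparison()] objects.
#' @param n_perm permutations per comparison (default 9999).
#' @param seed master seed for the permutation streams.
#' @return a `stats_table`: named list of per-comparison data.frames with
#'   columns `feature_id`, `p_anova`, `p_perm`, `q_by`, `fold_change`,
#'   `mean_left`, `mean_right`.
#' @export
run_univariate <- function(m, comparisons, n_perm = 9999L, seed = 1L) {
  out <- lapply(comparisons, function(comp) {
    idx <- comparison_rows(m, comp)
    sub <- lm_subset(m, samples = c(idx$left, idx$right))
    side <- factor(rep(c("left", "right"), c(length(idx$left), length(idx$right))))
    an <- anova_per_feature(sub, side)
    fc <- fold_change_signed(m, comp)
    pt <- permutation_test(m, comp, n_perm = n_perm, seed = seed)
    data.frame(feature_id = an$feature_id, p_anova = an$p, p_perm = pt$p,
               q_by = by_adjust(pt$p), fold_change = fc$fold_change,
               mean_left = fc$mean_left, mean_right = fc$mean_right,
               stringsAsFactors = FALSE)
  })
  names(out) <- vapply(comparisons, `[[`, character(1), "name")
  structure(out, class = "stats_table")
}

#' @export
print.stats_table <- function(x, alpha = 0.05, ...) {
  cat(sprintf("stats_table: %d comparisons x %d features\n",
              length(x), nrow(x[[1]])))
  for (nm in names(x))
    cat(sprintf("  %-28s %4d features with p_anova < %.2f\n",
                nm, sum(x[[nm]]$p_anova < alpha), alpha))
  invisible(x)
}

#' Candidate features: union of per-comparison ANOVA hits
#'
#' Screening is on unadjusted ANOVA p-values (adjustment is deliberately
#' deferred at the candidate stage); the union across comparisons
#' deduplicates features significant in several comparisons.
#'
#' @param tables a `stats_table` from [run_univariate()].
#' @param alpha screening threshold (default 0.05).
#' @return list with `selected` (feature ids), `per_comparison` (named hit
#'   counts), `union_size`.
#' @export
select_candidates <- function(tables, alpha = 0.05) {
  stopifnot(inherits(tables, "stats_table"))
  hits <- lapply(tables, function(tb) tb$feature_id[tb$p_anova < alpha])
  selected <- unique(unlist(hits, use.names = FALSE))
  if (!length(selected)) warning("no candidate features at alpha = ", alpha)
  list(selected = selected,
       per_comparison = vapply(hits, length, integer(1)),
       union_size = length(selected))
}
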