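test_that("baseline subtraction flattens constants and preserves apex height", {
  flat <- data.frame(mz = seq(1000, 2000, by = 1), intensity = 7)
  out <- subtract_baseline(flat, window = 100)
  expect_true(all(out$intensity == 0))

  zero <- data.frame(mz = seq(1000, 2000, by = 1), intensity = 0)
  expect_true(all(subtract_baseline(zero, window = 50)$intensity == 0))

  s <- gaussian_spectrum(center = 3000, amp = 100, sigma = 5, offset = 10)
  out <- subtract_baseline(s, window = 100)
  apex <- max(out$intensity)
  expect_lt(abs(apex - 100) / 100, 0.05)

  expect_error(subtract_baseline(data.frame(mz = numeric(0),
                                            intensity = numeric(0)), 10),
               "empty")
})

test_that("TIC normalization equalizes totals at the set mean", {
  meta <- data.frame(sample_id = c("a", "b"), dose_gy = 0, day = 3L,
                     batch = 1L, is_qc_pool = FALSE)
  mk <- function(total, n = 100) data.frame(mz = seq_len(n),
                                            intensity = rep(total / n, n))
  ss <- spectrum_set(list(mk(10), mk(30)), meta)
  out <- tic_normalize(ss)
  totals <- vapply(out$spectra, function(s) sum(s$intensity), numeric(1))
  expect_equal(unname(totals), c(20, 20))

  # identical spectra and single spectrum: unchanged
  ss2 <- spectrum_set(list(mk(10), mk(10)), meta)
  expect_equal(tic_normalize(ss2)$spectra[[1]]$intensity,
               ss2$spectra[[1]]$intensity)
  ss1 <- spectrum_set(list(mk(12)), meta[1, ])
  expect_equal(tic_normalize(ss1)$spectra[[1]]$intensity,
               ss1$spectra[[1]]$intensity)

  ss0 <- spectrum_set(list(mk(10), data.frame(mz = 1:100, intensity = 0)), meta)
  expect_error(tic_normalize(ss0), "b")
})

test_that("peak detection thresholds on S/N with a MAD noise estimate", {
  s <- gaussian_spectrum(amp = 100, sigma = 5, noise_sd = 1, seed = 3)
  pk <- detect_peaks(s, snr_threshold = 2.5)
  near <- pk[abs(pk$mz - 3000) < 20, ]
  expect_equal(nrow(near), 1L)
  expect_gt(near$snr, 80)
  expect_lt(near$snr, 120)

  weak <- gaussian_spectrum(amp = 2, sigma = 5, noise_sd = 1, seed = 4)
  pk2 <- detect_peaks(weak, snr_threshold = 2.5)
  expect_false(any(abs(pk2$mz - 3000) < 20 & pk2$intensity > 1.9))

  flat <- data.frame(mz = 1:100, intensity = rep(0, 100))
  expect_equal(nrow(detect_peaks(flat, 2.5)), 0L)
  expect_error(detect_peaks(data.frame(mz = c(2, 1), intensity = c(0, 0)), 1),
               "ascending")
})

test_that("the cluster window is 0.3% of mass: 10 Da merges, 200 Da splits", {
  # peaks at 7000 and 7010 across samples: gap 10 < 21 Da -> one cluster
  tab <- data.frame(sample = rep(1:4, each = 2),
                    mz = rep(c(7000, 7010), 4),
                    intensity = 50, snr = 10)
  pm <- cluster_peaks(peaklists_from_table(tab, 4), cluster_params())
  expect_length(pm$cluster_mz, 1L)

  tab2 <- transform(tab, mz = rep(c(7000, 7200), 4))  # 200 > 21.3 Da
  pm2 <- cluster_peaks(peaklists_from_table(tab2, 4), cluster_params())
  expect_length(pm2$cluster_mz, 2L)
})

test_that("a 51/128-sample peak fails the first pass but is completed", {
  # presence 39.8% < 50% blocks pass 1; >= 10% at S/N >= 3 admits pass 2
  tab <- data.frame(sample = 1:51, mz = 5000, intensity = 40, snr = 4)
  # an anchor cluster everyone shares, so pass 1 is non-trivial
  anchor <- data.frame(sample = 1:128, mz = 3000, intensity = 60, snr = 8)
  pm <- cluster_peaks(peaklists_from_table(rbind(anchor, tab), 128),
                      cluster_params())
  expect_length(pm$cluster_mz, 2L)
  expect_equal(pm$provenance[order(pm$cluster_mz)], c("first", "completion"))

  # at S/N below the completion threshold the same peak vanishes entirely
  tab_low <- transform(tab, snr = 2.8)
  pm2 <- cluster_peaks(peaklists_from_table(rbind(anchor, tab_low), 128),
                       cluster_params())
  expect_length(pm2$cluster_mz, 1L)
})

test_that("cluster masses are intensity-weighted and missing values fall to 0", {
  tab <- data.frame(sample = 1:2, mz = c(7000, 7010),
                    intensity = c(30, 10), snr = 10)
  pm <- cluster_peaks(peaklists_from_table(tab, 2), cluster_params())
  expect_equal(pm$cluster_mz, (7000 * 30 + 7010 * 10) / 40)
  expect_equal(dim(pm$values), c(1L, 2L))
  expect_equal(sort(pm$values[1, ]), c(10, 30))

  # without spectra, a sample missing the peak gets 0
  tab3 <- data.frame(sample = 1:3, mz = c(7000, 7004, 7008),
                     intensity = 20, snr = 10)
  pl <- peaklists_from_table(tab3, 4)
  pm3 <- cluster_peaks(pl, cluster_params())
  expect_equal(pm3$values[1, 4], 0)
})

test_that("clustering is invariant to sample order", {
  set.seed(31)
  tab <- data.frame(sample = rep(1:10, each = 3),
                    mz = rep(c(3000, 5000, 9000), 10) + rnorm(30, 0, 2),
                    intensity = runif(30, 20, 60), snr = runif(30, 3, 9))
  pl <- peaklists_from_table(tab, 10)
  pm_a <- cluster_peaks(pl, cluster_params())
  perm <- sample(10)
  pm_b <- cluster_peaks(pl[perm], cluster_params())
  expect_equal(sort(pm_a$cluster_mz), sort(pm_b$cluster_mz))
})

test_that("every detected peak lands in at most one cluster", {
  set.seed(17)
  tab <- data.frame(sample = rep(1:6, each = 4),
                    mz = rep(c(2000, 2004, 6000, 6010), 6) + rnorm(24, 0, 1),
                    intensity = runif(24, 10, 50), snr = runif(24, 3, 9))
  pl <- peaklists_from_table(tab, 6)
  pm <- cluster_peaks(pl, cluster_params())
  # per sample, the count of member intensities across clusters cannot
  # exceed its peak count
  for (i in 1:6) {
    n_members <- sum(pm$values[, i] %in% pl[[i]]$intensity)
    expect_lte(n_members, nrow(pl[[i]]))
  }
  # adjacent representative masses are separated by more than the window
  if (length(pm$cluster_mz) > 1)
    expect_true(all(diff(pm$cluster_mz) >
                      0.003 * pm$cluster_mz[-length(pm$cluster_mz)]))
})

test_that("QC coefficient of variation uses the n-1 sd and flags zero means", {
  pm <- structure(list(cluster_mz = c(3000, 5000, 7000),
                       values = rbind(c(10, 10, 10, 1),
                                      c(8, 10, 12, 1),
                                      c(0, 0, 0, 5)),
                       provenance = rep("first", 3),
                       sample_ids = c("q1", "q2", "q3", "x")),
                  class = "peak_matrix")
  out <- qc_cv(pm, c("q1", "q2", "q3"))
  expect_equal(out$cv[1], 0)
  expect_equal(out$cv[2], 0.2)               # sd(8,10,12)/10 = 2/10
  expect_true(is.na(out$cv[3]))
  expect_equal(out$flagged, 3L)
  expect_equal(out$mean_cv, 0.1)
  expect_error(qc_cv(pm, c("q1", "q2")), ">= 3")
})
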