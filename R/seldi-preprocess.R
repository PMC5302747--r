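#' Clustering parameters for cross-spectrum peak alignment
#'
#' The two-pass scheme used for chip-array profiling: a first pass keeps
#' peak clusters detected at S/N >= `first_pass_snr` in at least
#' `first_pass_min_presence` of the spectra; a completion pass then admits
#' additional clusters from peaks at S/N >= `completion_snr` present in at
#' least `completion_min_presence` of the spectra.  Peaks are grouped within
#' a mass window of `window_frac` of m/z (default 0.3% of mass).  The S/N
#' thresholds are numbers, not percentages: the printed "%"s in vendor
#' protocols are typographical (an S/N cut of 0.025 would detect noise).
#'
#' @param first_pass_snr S/N threshold for the first pass (default 2.5).
#' @param first_pass_min_presence minimum fraction of spectra (default 0.50).
#' @param completion_snr S/N threshold for the completion pass (default 3.0).
#' @param completion_min_presence minimum fraction of spectra (default 0.10).
#' @param window_frac cluster mass window as a fraction of m/z (default 0.003).
#' @return a `cluster_params` list.
#' @export
cluster_params <- function(first_pass_snr = 2.5, first_pass_min_presence = 0.50,
                           completion_snr = 3.0, completion_min_presence = 0.10,
                           window_frac = 0.003) {
  if (window_frac <= 0) abort("window_frac must be > 0")
  if (first_pass_min_presence <= 0 || first_pass_min_presence > 1 ||
      completion_min_presence <= 0 || completion_min_presence > 1)
    abort("presence fractions must lie in (0, 1]")
  structure(list(first_pass_snr = first_pass_snr,
                 first_pass_min_presence = first_pass_min_presence,
                 completion_snr = completion_snr,
                 completion_min_presence = completion_min_presence,
                 window_frac = window_frac),
            class = "cluster_params")
}

# centered rolling minimum/maximum, edge-padded, via embed/pmin (vectorised)
rolling_min <- function(x, k) {
  h <- (k - 1L) %/% 2L
  xp <- c(rep(x[1], h), x, rep(x[length(x)], h))
  do.call(pmin, as.data.frame(embed(xp, k)))[seq_along(x)]
}

rolling_max <- function(x, k) -rolling_min(-x, k)

# centered moving average, edge-padded
moving_avg <- function(x, k) {
  h <- (k - 1L) %/% 2L
  xp <- c(rep(x[1], h), x, rep(x[length(x)], h))
  as.numeric(stats::filter(xp, rep(1 / k, k), sides = 2))[(h + 1):(h + length(x))]
}

#' Subtract a morphological-opening baseline from a spectrum
#'
#' The baseline is the morphological opening of the trace — a rolling
#' minimum followed by a rolling maximum over the same `window` (Da) —
#' lightly smoothed by a moving average; output intensities are clipped at
#' zero.  The opening reconstructs any monotone or slowly varying baseline
#' without the edge bias of a plain rolling minimum, while peaks narrower
#' than the window are removed from it entirely, so apex heights are
#' preserved.  The window must be wide relative to peak widths and narrow
#' relative to the baseline's variation.
#'
#' @param s a spectrum: data.frame with ascending `mz` and `intensity`.
#' @param window baseline window in Da (default 200).
#' @return the baseline-subtracted spectrum (same shape).
#' @export
subtract_baseline <- function(s, window = 200) {
  if (window <= 0) abort("window must be > 0")
  if (!nrow(s)) abort("empty spectrum")
  step <- if (nrow(s) > 1) (s$mz[nrow(s)] - s$mz[1]) / (nrow(s) - 1) else 1
  k <- max(3L, as.integer(round(window / step)))
  if (k %% 2L == 0L) k <- k + 1L
  k <- min(k, if (nrow(s) %% 2L) nrow(s) else nrow(s) - 1L)
  k_smooth <- max(3L, k %/% 4L)
  if (k_smooth %% 2L == 0L) k_smooth <- k_smooth + 1L
  base <- moving_avg(rolling_max(rolling_min(s$intensity, k), k), k_smooth)
  r <- s$intensity - base
  # the opening of a noisy trace tracks the lower noise envelope, a few
  # noise-sd below the floor; a wide running median of the residual (peaks
  # occupy a small fraction of it) recentres the floor at zero
  k_med <- min(3L * k, if (nrow(s) %% 2L) nrow(s) else nrow(s) - 1L)
  if (k_med %% 2L == 0L) k_med <- k_med - 1L
  if (k_med >= 3L) r <- r - stats::runmed(r, k_med)
  data.frame(mz = s$mz, intensity = pmax(0, r))
}

#' Total-ion-current normalization of a spectrum set
#'
#' Each spectrum is rescaled so its total intensity equals the mean total
#' ion current across the set, removing per-spot variation in desorption
#' efficiency and laser energy.
#'
#' @param ss a [spectrum_set()].
#' @return a [spectrum_set()] with rescaled intensities.
#' @export
tic_normalize <- function(ss) {
  stopifnot(inherits(ss, "spectrum_set"))
  totals <- vapply(ss$spectra, function(s) sum(s$intensity), numeric(1))
  bad <- which(totals <= 0)
  if (length(bad))
    abort("zero or negative total ion current in sample(s): %s",
          paste(ss$meta$sample_id[bad], collapse = ", "))
  target <- mean(totals)
  spectra <- mapply(function(s, tot) {
    s$intensity <- s$intensity * (target / tot)
    s
  }, ss$spectra, totals, SIMPLIFY = FALSE)
  spectrum_set(spectra, ss$meta)
}

# robust noise scale of a running-median-detrended trace.  The estimator is
# the median of the POSITIVE detrended deviations scaled to a Gaussian sd
# (median of the positive half of N(0, s) is 0.6745 s): unlike the plain
# MAD it stays consistent when the trace has been clipped at zero, which
# zero-inflates the negative half
spectrum_noise <- function(intensity, k = 31L) {
  n <- length(intensity)
  k <- min(k, if (n %% 2L) n else n - 1L)
  d <- if (k < 3L) intensity - stats::median(intensity)
       else intensity - stats::runmed(intensity, k)
  pos <- d[d > 0]
  if (!length(pos)) return(0)
  stats::median(pos) / 0.6744898
}

#' Detect peaks in a baseline-subtracted spectrum
#'
#' Local maxima of the lightly smoothed trace (a short moving average, which
#' suppresses single-point noise bumps on peak flanks and at weak apexes)
#' whose signal-to-noise ratio meets `snr_threshold`.  Intensity is the
#' smoothed apex height; noise is the median absolute deviation (scaled to a
#' Gaussian sd) of the raw spectrum after detrending by a running median, so
#' isolated peaks do not inflate the noise estimate.
#'
#' @param s a spectrum data.frame (`mz`, `intensity`), baseline-subtracted.
#' @param snr_threshold minimum S/N for a reported peak (default 2.5).
#' @param smooth_points odd width of the pre-detection moving average
#'   (default 5; 1 disables smoothing).
#' @return data.frame with columns `mz`, `intensity`, `snr`, sorted by mz.
#' @export
detect_peaks <- function(s, snr_threshold = 2.5, smooth_points = 5L) {
  if (is.unsorted(s$mz, strictly = TRUE)) abort("mz must be strictly ascending")
  y <- s$intensity
  n <- length(y)
  if (n < 3L) return(data.frame(mz = numeric(0), intensity = numeric(0),
                                snr = numeric(0)))
  noise <- spectrum_noise(y)
  ys <- if (smooth_points > 1L) moving_avg(y, smooth_points) else y
  is_max <- c(FALSE, ys[2:(n - 1)] > ys[1:(n - 2)] & ys[2:(n - 1)] >= ys[3:n] &
                ys[2:(n - 1)] > 0, FALSE)
  idx <- which(is_max)
  snr <- if (noise > 0) ys[idx] / noise else rep(Inf, length(idx))
  keep <- snr >= snr_threshold
  data.frame(mz = s$mz[idx[keep]], intensity = ys[idx[keep]], snr = snr[keep])
}

# single-linkage grouping of pooled sorted peaks: split where the gap between
# consecutive peaks exceeds window_frac * mz
gap_cluster <- function(pool, window_frac) {
  if (!nrow(pool)) return(integer(0))
  o <- order(pool$mz)
  mz <- pool$mz[o]
  brk <- c(FALSE, diff(mz) > window_frac * mz[-length(mz)])
  cl_sorted <- cumsum(brk) + 1L
  cl <- integer(nrow(pool))
  cl[o] <- cl_sorted
  cl
}

# summarise one cluster: representative mass = intensity-weighted mean,
# presence = fraction of distinct samples contributing a member peak
cluster_summary <- function(pool, cl, n_samples) {
  if (!length(cl)) {
    return(data.frame(cluster_mz = numeric(0), presence = numeric(0)))
  }
  sp <- split(seq_len(nrow(pool)), cl)
  data.frame(
    cluster_mz = vapply(sp, function(i)
      stats::weighted.mean(pool$mz[i], pool$intensity[i]), numeric(1)),
    presence = vapply(sp, function(i)
      length(unique(pool$sample[i])), numeric(1)) / n_samples,
    id = as.integer(names(sp)))
}

#' Two-pass cross-spectrum peak clustering into a peak matrix
#'
#' Pass 1 pools peaks at S/N >= `first_pass_snr`, groups them by
#' single-linkage within a `window_frac`-of-mass window, and keeps clusters
#' present in at least `first_pass_min_presence` of the samples.  Pass 2
#' takes the remaining peaks at S/N >= `completion_snr` and admits further
#' clusters present in at least `completion_min_presence` of the samples.
#' For each sample missing a member peak the cluster intensity is read from
#' that sample's spectrum at the representative mass (linear interpolation)
#' when `spectra` is supplied, else set to 0.
#'
#' @param peaklists named list (one per sample) of [detect_peaks()] outputs.
#' @param params a [cluster_params()].
#' @param spectra optional [spectrum_set()] with the (processed) spectra the
#'   peaks were detected in, used for missing-value fill-in.
#' @return a `peak_matrix`: list with `cluster_mz` (ascending), `values`
#'   (clusters x samples), `provenance` (`"first"`/`"completion"` per
#'   cluster), `sample_ids`.
#' @export
cluster_peaks <- function(peaklists, params = cluster_params(), spectra = NULL) {
  stopifnot(inherits(params, "cluster_params"))
  n_samples <- length(peaklists)
  if (n_samples < 2L) abort("need at least 2 samples to cluster")
  if (is.null(names(peaklists)))
    names(peaklists) <- sprintf("sample_%03d", seq_len(n_samples))
  pool <- do.call(rbind, lapply(seq_along(peaklists), function(i) {
    pl <- peaklists[[i]]
    if (!nrow(pl)) return(NULL)
    cbind(pl, sample = i)
  }))
  if (is.null(pool)) pool <- data.frame(mz = numeric(0), intensity = numeric(0),
                                        snr = numeric(0), sample = integer(0))

  # pass 1
  p1 <- pool[pool$snr >= params$first_pass_snr, , drop = FALSE]
  cl1 <- gap_cluster(p1, params$window_frac)
  sum1 <- cluster_summary(p1, cl1, n_samples)
  keep1 <- sum1[sum1$presence >= params$first_pass_min_presence, , drop = FALSE]
  member1 <- cl1 %in% keep1$id

  # pass 2: peaks at completion S/N not claimed by a kept first-pass cluster
  claimed <- paste(p1$sample[member1], p1$mz[member1])
  p2 <- pool[pool$snr >= params$completion_snr &
               !(paste(pool$sample, pool$mz) %in% claimed), , drop = FALSE]
  cl2 <- gap_cluster(p2, params$window_frac)
  sum2 <- cluster_summary(p2, cl2, n_samples)
  keep2 <- sum2[sum2$presence >= params$completion_min_presence, , drop = FALSE]
  # drop completion clusters falling inside the window of a kept pass-1 mass
  if (nrow(keep1) && nrow(keep2)) {
    near <- vapply(keep2$cluster_mz, function(m)
      any(abs(keep1$cluster_mz - m) <= params$window_frac * m), logical(1))
    keep2 <- keep2[!near, , drop = FALSE]
  }

  clusters <- rbind(
    if (nrow(keep1)) data.frame(cluster_mz = keep1$cluster_mz, pass = "first",
                                pool = "p1", id = keep1$id),
    if (nrow(keep2)) data.frame(cluster_mz = keep2$cluster_mz, pass = "completion",
                                pool = "p2", id = keep2$id))
  if (is.null(clusters))
    clusters <- data.frame(cluster_mz = numeric(0), pass = character(0),
                           pool = character(0), id = integer(0))
  ord <- order(clusters$cluster_mz)
  clusters <- clusters[ord, , drop = FALSE]

  values <- matrix(0, nrow(clusters), n_samples)
  for (r in seq_len(nrow(clusters))) {
    if (clusters$pool[r] == "p1") {
      sub <- p1[cl1 == clusters$id[r], , drop = FALSE]
    } else {
      sub <- p2[cl2 == clusters$id[r], , drop = FALSE]
    }
    agg <- tapply(sub$intensity, sub$sample, max)
    values[r, as.integer(names(agg))] <- agg
    miss <- setdiff(seq_len(n_samples), as.integer(names(agg)))
    if (length(miss) && !is.null(spectra)) {
      for (i in miss) {
        sp <- spectra$spectra[[i]]
        values[r, i] <- max(0, stats::approx(sp$mz, sp$intensity,
                                             xout = clusters$cluster_mz[r],
                                             rule = 2)$y)
      }
    }
  }
  structure(list(cluster_mz = clusters$cluster_mz,
                 values = values,
                 provenance = clusters$pass,
                 sample_ids = names(peaklists)),
            class = "peak_matrix")
}

#' @export
print.peak_matrix <- function(x, ...) {
  cat(sprintf("peak_matrix: %d clusters x %d samples (%d first pass, %d completion)\n",
              length(x$cluster_mz), ncol(x$values),
              sum(x$provenance == "first"), sum(x$provenance == "completion")))
  invisible(x)
}

#' Per-cluster coefficient of variation over QC-pool replicates
#'
#' Technical reproducibility of the peak matrix, estimated from the pooled
#' standard spotted on every array: per-cluster sd/mean (sample sd, n-1)
#' over the QC columns, and their mean.  Clusters with zero QC mean are
#' flagged and excluded from the summary.
#'
#' @param pm a `peak_matrix`.
#' @param qc_sample_ids sample ids of the QC-pool columns (>= 3).
#' @return list with `cv` (per cluster; NA where flagged), `mean_cv`, and
#'   `flagged` (indices of zero-mean clusters).
#' @export
qc_cv <- function(pm, qc_sample_ids) {
  stopifnot(inherits(pm, "peak_matrix"))
  cols <- match(qc_sample_ids, pm$sample_ids)
  if (anyNA(cols)) abort("unknown QC sample id(s): %s",
                         paste(qc_sample_ids[is.na(cols)], collapse = ", "))
  if (length(cols) < 3L) abort("need >= 3 QC samples")
  q <- pm$values[, cols, drop = FALSE]
  m <- rowMeans(q)
  s <- apply(q, 1, stats::sd)
  cv <- ifelse(m == 0, NA_real_, s / m)
  list(cv = cv, mean_cv = mean(cv, na.rm = TRUE), flagged = which(m == 0))
}

#' Full spectral preprocessing: baseline, TIC, detection, clustering
#'
#' Applies [subtract_baseline()] and [tic_normalize()] to every spectrum,
#' detects peaks at the looser of the two pass S/N thresholds, clusters
#' across spectra with [cluster_peaks()], and returns the peak matrix
#' together with a [labeled_matrix()] view (clusters as features) carrying
#' the sample metadata.
#'
#' @param ss a [spectrum_set()] of raw spectra.
#' @param params a [cluster_params()].
#' @param baseline_window baseline window in Da (default 200).
#' @return list with `peak_matrix`, `matrix` (a [labeled_matrix()]), and
#'   `qc` (the [qc_cv()] summary, or NULL when fewer than 3 QC spectra).
#' @export
seldi_preprocess <- function(ss, params = cluster_params(), baseline_window = 200) {
  stopifnot(inherits(ss, "spectrum_set"))
  proc <- lapply(ss$spectra, subtract_baseline, window = baseline_window)
  proc_ss <- spectrum_set(proc, ss$meta)
  proc_ss <- tic_normalize(proc_ss)
  detect_thr <- min(params$first_pass_snr, params$completion_snr)
  peaklists <- lapply(proc_ss$spectra, detect_peaks, snr_threshold = detect_thr)
  pm <- cluster_peaks(peaklists, params, spectra = proc_ss)
  lmx <- labeled_matrix(t(pm$values), sprintf("cluster_%.1f", pm$cluster_mz),
                        ss$meta)
  qc_ids <- ss$meta$sample_id[ss$meta$is_qc_pool]
  qc <- if (length(qc_ids) >= 3) qc_cv(pm, qc_ids) else NULL
  list(peak_matrix = pm, matrix = lmx, qc = qc)
}
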