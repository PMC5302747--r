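#' Configuration for the SELDI-TOF spectrum simulator
#'
#' Emulates low-mass-range serum profiles: Gaussian peaks on a smooth
#' exponentially decaying chemical-noise baseline plus white detector noise,
#' with a per-spectrum multiplicative mass-calibration jitter.  Defaults give
#' 120 peaks across 1,800-10,000 Da, 32 samples per dose group, and a pooled
#' QC standard replicated across arrays with ~15% technical CV — the
#' reproducibility regime reported for the chip arrays (10-20% CV).
#'
#' @param mz_min,mz_max mass range in Da (defaults 1800 and 10000).
#' @param grid_points number of points of the shared ascending m/z grid
#'   (default 8200, ~1 Da spacing).
#' @param true_peaks data.frame with columns `mz` (Da, ascending),
#'   `mean_intensity`, `cv` (biological coefficient of variation).  Default:
#'   120 peaks spread over the range with log-normal intensities.
#' @param peak_width_frac Gaussian peak sigma as a fraction of m/z
#'   (default 0.0012, matching TOF resolution at these masses).
#' @param mass_jitter_frac per-spectrum multiplicative calibration error,
#'   uniform in +/- this fraction (default 0.001 = 0.1%).
#' @param noise_sd white-noise sd (default 1).
#' @param baseline_amplitude amplitude of the decaying baseline (default 30).
#' @param n_per_group samples per dose group (default 32).
#' @param n_qc_replicates pooled-standard spectra (default 8).
#' @param doses dose levels in Gy (default 0, 20, 40, 80).
#' @param qc_cv technical CV applied to QC-pool peak intensities
#'   (default 0.15).
#' @param seed integer seed.
#' @return a `seldi_sim_config` list.
#' @export
seldi_sim_config <- function(mz_min = 1800, mz_max = 10000, grid_points = 8200L,
                             true_peaks = NULL, peak_width_frac = 0.0012,
                             mass_jitter_frac = 0.001, noise_sd = 1,
                             baseline_amplitude = 30, n_per_group = 32L,
                             n_qc_replicates = 8L, doses = c(0, 20, 40, 80),
                             qc_cv = 0.15, seed = 1L) {
  if (mz_min >= mz_max) abort("mz_min must be below mz_max")
  if (is.null(true_peaks)) true_peaks <- default_true_peaks(mz_min, mz_max, seed)
  true_peaks <- as.data.frame(true_peaks)
  stopifnot(all(c("mz", "mean_intensity", "cv") %in% names(true_peaks)))
  if (is.unsorted(true_peaks$mz, strictly = TRUE))
    abort("true_peaks must be strictly ascending in mz")
  if (any(true_peaks$cv < 0)) abort("peak cv must be >= 0")
  step <- (mz_max - mz_min) / (grid_points - 1)
  if (any(diff(true_peaks$mz) < 3 * step))
    abort("configuration error: grid too coarse to resolve adjacent peaks (spacing < 3 grid steps)")
  structure(list(mz_min = mz_min, mz_max = mz_max,
                 grid_points = as.integer(grid_points),
                 true_peaks = true_peaks, peak_width_frac = peak_width_frac,
                 mass_jitter_frac = mass_jitter_frac, noise_sd = noise_sd,
                 baseline_amplitude = baseline_amplitude,
                 n_per_group = as.integer(n_per_group),
                 n_qc_replicates = as.integer(n_qc_replicates),
                 doses = doses, qc_cv = qc_cv, seed = as.integer(seed)),
            class = "seldi_sim_config")
}

# default peak map: masses spread with log-uniform-ish spacing, intensities
# log-normal around 40 (well above noise), biological cv 0.25
default_true_peaks <- function(mz_min, mz_max, seed, n_peaks = 120L) {
  with_seed(derive_seed(seed, "peakmap"), {
    span <- mz_max - mz_min
    base <- seq(mz_min + 0.02 * span, mz_max - 0.02 * span, length.out = n_peaks)
    mz <- sort(base + stats::runif(n_peaks, -0.3, 0.3) * span / n_peaks / 2)
    data.frame(mz = mz,
               mean_intensity = exp(stats::rnorm(n_peaks, log(40), 0.5)),
               cv = 0.25)
  })
}

#' A set of spectra on per-sample m/z grids
#'
#' @param spectra named list of data.frames with ascending `mz` and
#'   non-negative-length `intensity` columns.
#' @param meta sample metadata data.frame (same columns as
#'   [labeled_matrix()] metadata), one row per spectrum, in list order.
#' @return an object of class `spectrum_set`.
#' @export
spectrum_set <- function(spectra, meta) {
  stopifnot(is.list(spectra), nrow(meta) == length(spectra))
  for (i in seq_along(spectra)) {
    s <- spectra[[i]]
    if (!all(c("mz", "intensity") %in% names(s)))
      abort("spectrum %d lacks mz/intensity columns", i)
    if (is.unsorted(s$mz, strictly = TRUE))
      abort("spectrum %d: mz must be strictly ascending", i)
  }
  names(spectra) <- meta$sample_id
  structure(list(spectra = spectra, meta = meta), class = "spectrum_set")
}

#' @export
print.spectrum_set <- function(x, ...) {
  cat(sprintf("spectrum_set: %d spectra, %d points each (%d QC pool)\n",
              length(x$spectra), nrow(x$spectra[[1]]), sum(x$meta$is_qc_pool)))
  invisible(x)
}

#' @export
length.spectrum_set <- function(x) length(x$spectra)

#' Simulate SELDI-TOF serum spectra with the study's group structure
#'
#' One spectrum per sample (`length(doses) * n_per_group`) plus
#' `n_qc_replicates` pooled-QC spectra.  Each sample draws per-peak
#' intensities log-normally around the peak's `mean_intensity` at its `cv`;
#' the QC pool uses the mean intensity of every peak with only technical
#' noise (`qc_cv`) applied.  A per-spectrum calibration factor uniform in
#' +/- `mass_jitter_frac` shifts all peak positions multiplicatively, so
#' every true peak stays a local maximum within that fraction of its nominal
#' mass.  Returns the spectra and, as the latent truth for oracle
#' comparisons, the noiseless per-sample peak-intensity matrix.
#'
#' @param config a [seldi_sim_config()].
#' @param day sampling day recorded in the metadata (default 3).
#' @return list with elements `spectra` (a [spectrum_set()]) and
#'   `truth` (a [labeled_matrix()] of true peak intensities, features named
#'   `peak_<mz>`).
#' @export
generate_seldi_spectra <- function(config, day = 3L) {
  stopifnot(inherits(config, "seldi_sim_config"))
  with_seed(derive_seed(config$seed, "seldi", day), {
    grid <- seq(config$mz_min, config$mz_max, length.out = config$grid_points)
    pk <- config$true_peaks
    n_pk <- nrow(pk)
    dose_v <- rep(config$doses, each = config$n_per_group)
    batch_v <- rep(rep(1:2, length.out = config$n_per_group),
                   times = length(config$doses))
    ids <- sprintf("d%d_dose%03d_s%02d", day, dose_v,
                   stats::ave(seq_along(dose_v), dose_v, FUN = seq_along))
    n_qc <- config$n_qc_replicates
    meta <- data.frame(
      sample_id = c(ids, if (n_qc) sprintf("qc_pool_%02d", seq_len(n_qc))),
      dose_gy = c(dose_v, rep(NA_real_, n_qc)),
      day = as.integer(day),
      batch = c(batch_v, rep(1L, n_qc)),
      is_qc_pool = c(rep(FALSE, length(ids)), rep(TRUE, n_qc)),
      stringsAsFactors = FALSE)
    meta$dose_gy[is.na(meta$dose_gy)] <- 0   # QC pool carries no dose; keep numeric

    lsd_bio <- sqrt(log(1 + pk$cv^2))        # log-normal sd giving the target CV
    lsd_qc <- sqrt(log(1 + config$qc_cv^2))
    truth <- matrix(0, nrow(meta), n_pk)
    spectra <- vector("list", nrow(meta))
    baseline <- config$baseline_amplitude *
      exp(-(grid - config$mz_min) / (0.25 * (config$mz_max - config$mz_min)))
    for (i in seq_len(nrow(meta))) {
      if (meta$is_qc_pool[i]) {
        amp <- pk$mean_intensity * exp(stats::rnorm(n_pk, -lsd_qc^2 / 2, lsd_qc))
      } else {
        amp <- pk$mean_intensity * exp(stats::rnorm(n_pk, -lsd_bio^2 / 2, lsd_bio))
      }
      jit <- 1 + stats::runif(1, -config$mass_jitter_frac, config$mass_jitter_frac)
      signal <- numeric(length(grid))
      for (j in seq_len(n_pk)) {
        mu <- pk$mz[j] * jit
        sig <- config$peak_width_frac * mu
        # evaluate only within +/- 5 sigma: spectra are wide, peaks are narrow
        idx <- which(grid >= mu - 5 * sig & grid <= mu + 5 * sig)
        signal[idx] <- signal[idx] + amp[j] * exp(-((grid[idx] - mu)^2) / (2 * sig^2))
      }
      intensity <- signal + baseline + stats::rnorm(length(grid), 0, config$noise_sd)
      spectra[[i]] <- data.frame(mz = grid, intensity = intensity)
      truth[i, ] <- amp
    }
    list(spectra = spectrum_set(spectra, meta),
         truth = labeled_matrix(truth, sprintf("peak_%.1f", pk$mz), meta))
  })
}

#' Write a spectrum set as per-sample two-column TSVs plus a manifest
#'
#' @param ss a [spectrum_set()].
#' @param dir output directory (created if needed).
#' @return the manifest path, invisibly.
#' @export
write_spectra <- function(ss, dir) {
  stopifnot(inherits(ss, "spectrum_set"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- sprintf("%s.tsv", ss$meta$sample_id)
  for (i in seq_along(ss$spectra)) {
    utils::write.table(ss$spectra[[i]], file.path(dir, files[i]), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  manifest <- cbind(file = files, ss$meta)
  mpath <- file.path(dir, "manifest.tsv")
  utils::write.table(manifest, mpath, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(mpath)
}

#' Read a spectrum set written by [write_spectra()]
#'
#' @param dir directory containing `manifest.tsv` and the per-sample TSVs.
#' @return a [spectrum_set()].
#' @export
read_spectra <- function(dir) {
  mpath <- file.path(dir, "manifest.tsv")
  if (!file.exists(mpath)) abort("no manifest.tsv in %s", dir)
  manifest <- utils::read.table(mpath, sep = "\t", header = TRUE,
                                stringsAsFactors = FALSE)
  spectra <- lapply(manifest$file, function(f)
    utils::read.table(file.path(dir, f), sep = "\t", header = TRUE))
  meta <- manifest[, setdiff(names(manifest), "file"), drop = FALSE]
  spectrum_set(spectra, meta)
}
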