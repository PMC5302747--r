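#' Specify a planted marker feature
#'
#' A planted marker shifts group means multiplicatively on the linear
#' intensity scale.  Two modes mirror the two kinds of serum markers sought
#' in the study: `"exposure"` markers differ between sham-irradiated and any
#' irradiated group (triage), `"dose_monotone"` markers scale with the dose
#' level (prognosis): intensity is multiplied by `fold_change_per_level^k`
#' where k = 0, 1, 2, 3 for doses 0, 20, 40, 80 Gy.
#'
#' @param feature_index 1-based column index of the marker feature.
#' @param mode `"exposure"` or `"dose_monotone"`.
#' @param fold_change_per_level positive linear-scale ratio; values below 1
#'   encode down-regulation; must differ from 1.
#' @return a `marker_spec` list.
#' @export
marker_spec <- function(feature_index, mode = c("exposure", "dose_monotone"),
                        fold_change_per_level) {
  mode <- match.arg(mode)
  if (!is_number(fold_change_per_level) || fold_change_per_level <= 0)
    abort("fold_change_per_level must be a positive number")
  if (fold_change_per_level == 1)
    abort("a planted marker must have fold_change_per_level != 1")
  structure(list(feature_index = as.integer(feature_index), mode = mode,
                 fold_change_per_level = fold_change_per_level),
            class = "marker_spec")
}

#' Configuration for the 2D-DIGE spot-matrix simulator
#'
#' Defaults reproduce the study's design scale: 941 quantified spots and 16
#' mice per dose group at each sampling day, doses 0/20/40/80 Gy, two
#' independent experimental series (batches).  Intensities are log-normal:
#' each spot has a baseline log-mean drawn once from
#' N(`baseline_log_mean`, `baseline_log_sd`); each sample adds a per-batch
#' per-spot effect N(0, `batch_sd`) and residual noise N(0, `residual_sd`)
#' on the log scale.  Dye effects are folded into `batch_sd` (the dye-swap
#' design cancels them in expectation).
#'
#' @param n_features number of spot features (default 941).
#' @param n_per_group mice per dose group per day (default 16; must be >= 2).
#' @param doses dose levels in Gy (default 0, 20, 40, 80).
#' @param baseline_log_mean,baseline_log_sd log-scale mean and sd of spot
#'   baselines (defaults log(1000) and 1).
#' @param batch_sd log-scale sd of the per-batch per-spot effect (default
#'   0.10, a ~10% technical CV between series).
#' @param residual_sd log-scale residual sd (default 0.30, a ~30% biological
#'   CV typical of serum spot volumes).
#' @param markers list of [marker_spec()] objects (default none).
#' @param seed integer seed; generation is bit-reproducible from it.
#' @return a `dige_sim_config` list.
#' @export
dige_sim_config <- function(n_features = 941L, n_per_group = 16L,
                            doses = c(0, 20, 40, 80),
                            baseline_log_mean = log(1000), baseline_log_sd = 1,
                            batch_sd = 0.10, residual_sd = 0.30,
                            markers = list(), seed = 1L) {
  if (n_features < 1) abort("n_features must be >= 1")
  if (n_per_group < 2) abort("design error: n_per_group must be >= 2")
  if (batch_sd < 0 || residual_sd < 0 || baseline_log_sd < 0)
    abort("standard deviations must be >= 0")
  if (inherits(markers, "marker_spec")) markers <- list(markers)
  for (mk in markers) {
    if (!inherits(mk, "marker_spec")) abort("markers must be marker_spec objects")
    if (mk$feature_index < 1 || mk$feature_index > n_features)
      abort("configuration error: marker feature_index %d outside 1..%d",
            mk$feature_index, n_features)
  }
  structure(list(n_features = as.integer(n_features),
                 n_per_group = as.integer(n_per_group),
                 doses = doses,
                 baseline_log_mean = baseline_log_mean,
                 baseline_log_sd = baseline_log_sd,
                 batch_sd = batch_sd, residual_sd = residual_sd,
                 markers = markers, seed = as.integer(seed)),
            class = "dige_sim_config")
}

# log-scale additive effect of the planted markers for one dose:
# vector over features (0 for non-markers)
marker_log_effect <- function(config, dose) {
  eff <- numeric(config$n_features)
  pos_doses <- sort(config$doses[config$doses > 0])
  for (mk in config$markers) {
    lev <- if (dose == 0) 0
           else if (mk$mode == "exposure") 1
           else match(dose, pos_doses)
    eff[mk$feature_index] <- eff[mk$feature_index] +
      lev * log(mk$fold_change_per_level)
  }
  eff
}

#' Simulate a 2D-DIGE spot intensity matrix for one sampling day
#'
#' Generates (length(doses) x n_per_group) samples x n_features linear-scale
#' intensities.  Within each dose group, samples are balanced across the two
#' experimental series (batch 1/2).  Planted markers shift group means
#' multiplicatively (see [marker_spec()]).  The matrix of noiseless expected
#' intensities is attached as attribute `"truth"` together with the marker
#' indices, for oracle comparisons.
#'
#' @param config a [dige_sim_config()].
#' @param day sampling day post-irradiation (3 or 7).
#' @return a [labeled_matrix()] with `4 * n_per_group` rows.
#' @export
generate_dige_dataset <- function(config, day = 3L) {
  stopifnot(inherits(config, "dige_sim_config"))
  p <- config$n_features
  # spot baselines and series effects are properties of the spots and the
  # experimental series, not of the sampling day: day-3 and day-7 matrices
  # from one config share them, so the matrices can be pooled
  baseline <- with_seed(derive_seed(config$seed, "dige-baseline"),
    stats::rnorm(p, config$baseline_log_mean, config$baseline_log_sd))
  batch_eff <- with_seed(derive_seed(config$seed, "dige-batch"),
    rbind(stats::rnorm(p, 0, config$batch_sd),
          stats::rnorm(p, 0, config$batch_sd)))
  with_seed(derive_seed(config$seed, "dige", day), {
    doses <- config$doses
    n <- config$n_per_group
    dose_v <- rep(doses, each = n)
    batch_v <- rep(rep(1:2, length.out = n), times = length(doses))
    logv <- matrix(0, length(dose_v), p)
    for (i in seq_along(dose_v)) {
      logv[i, ] <- baseline + batch_eff[batch_v[i], ] +
        marker_log_effect(config, dose_v[i]) +
        stats::rnorm(p, 0, config$residual_sd)
    }
    meta <- data.frame(
      sample_id = sprintf("d%d_dose%03d_s%02d", day, dose_v,
                          stats::ave(seq_along(dose_v), dose_v, FUN = seq_along)),
      dose_gy = dose_v, day = as.integer(day), batch = batch_v,
      is_qc_pool = FALSE, stringsAsFactors = FALSE)
    out <- labeled_matrix(exp(logv), sprintf("spot_%04d", seq_len(p)), meta)
    truth_log <- vapply(dose_v, function(d) baseline + marker_log_effect(config, d),
                        numeric(p))
    attr(out, "truth") <- list(
      expected = exp(t(truth_log)),
      marker_index = vapply(config$markers, `[[`, integer(1), "feature_index"))
    out
  })
}
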