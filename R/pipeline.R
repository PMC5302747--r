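#' The study's seven standard group comparisons
#'
#' Triage comparisons (sham-irradiated vs all irradiated, per day and days
#' pooled) and prognosis comparisons (20 Gy vs pooled 40+80 Gy, and pooled
#' 20+40 Gy vs 80 Gy, per day).  The irradiated / higher-dose side is the
#' "left" (numerator) side of the fold-change convention.
#'
#' @param days the sampling days in the design (default 3 and 7).
#' @return list of [comparison()] objects, in the standard report order.
#' @export
study_comparisons <- function(days = c(3L, 7L)) {
  out <- list()
  for (d in days)
    out[[sprintf("NI_vs_IR_d%d", d)]] <-
      comparison(sprintf("NI_vs_IR_d%d", d),
                 left = cells(c(20, 40, 80), d), right = cells(0, d))
  if (length(days) > 1)
    out[["NI_vs_IR_all_days"]] <-
      comparison("NI_vs_IR_all_days",
                 left = cells(c(20, 40, 80), days), right = cells(0, days))
  for (d in days) {
    out[[sprintf("20_vs_4080_d%d", d)]] <-
      comparison(sprintf("20_vs_4080_d%d", d),
                 left = cells(c(40, 80), d), right = cells(20, d))
    out[[sprintf("2040_vs_80_d%d", d)]] <-
      comparison(sprintf("2040_vs_80_d%d", d),
                 left = cells(80, d), right = cells(c(20, 40), d))
  }
  out
}

#' Assemble a full study configuration
#'
#' Bundles the design, the simulation config, the comparisons, the selection
#' and evaluation settings, and a master seed from which every stage derives
#' its own substream.
#'
#' @param platform `"dige"` or `"seldi"`.
#' @param sim a [dige_sim_config()] or [seldi_sim_config()].
#' @param days sampling days (default 3 and 7).
#' @param comparisons list of [comparison()]s (default [study_comparisons()]).
#' @param selection_method `"plsda"`, `"rf"`, or both.
#' @param pls_params a [pls_select_params()].
#' @param rf_params an [rf_select_params()].
#' @param eval_method `"lda"` or `"logistic"` for panel refinement.
#' @param alpha ANOVA screening threshold (default 0.05).
#' @param n_perm permutations per comparison (default 9999).
#' @param train_frac evaluation train/test split fraction (default 0.70).
#' @param master_seed the single seed for the whole run.
#' @return a `study_config` list, validated against the declared design.
#' @export
study_config <- function(platform = c("dige", "seldi"), sim = NULL,
                         days = c(3L, 7L), comparisons = NULL,
                         selection_method = "plsda",
                         pls_params = pls_select_params(),
                         rf_params = rf_select_params(),
                         eval_method = c("lda", "logistic"),
                         alpha = 0.05, n_perm = 9999L, train_frac = 0.70,
                         master_seed = 1L) {
  platform <- match.arg(platform)
  eval_method <- match.arg(eval_method)
  if (is.null(sim))
    sim <- if (platform == "dige") dige_sim_config() else seldi_sim_config()
  if (is.null(comparisons)) comparisons <- study_comparisons(days)
  stopifnot(all(selection_method %in% c("plsda", "rf")))
  doses <- if (platform == "dige") sim$doses else sim$doses
  declared <- paste(rep(doses, times = length(days)),
                    rep(days, each = length(doses)))
  for (comp in comparisons) {
    used <- paste(c(comp$left$dose_gy, comp$right$dose_gy),
                  c(comp$left$day, comp$right$day))
    bad <- setdiff(used, declared)
    if (length(bad))
      abort("validation error: comparison '%s' references undeclared design cell(s): %s",
            comp$name, paste(bad, collapse = "; "))
  }
  structure(list(platform = platform, sim = sim, days = as.integer(days),
                 comparisons = comparisons,
                 selection_method = selection_method,
                 pls_params = pls_params, rf_params = rf_params,
                 eval_method = eval_method, alpha = alpha,
                 n_perm = as.integer(n_perm), train_frac = train_frac,
                 master_seed = as.integer(master_seed)),
            class = "study_config")
}

#' Read a study configuration from JSON or YAML
#'
#' The file holds named fields matching the [study_config()] arguments
#' (simulation blocks as nested objects; comparisons as objects with `name`,
#' `left`, `right` each listing `doses` and `days`).
#'
#' @param path a `.json` or `.yaml`/`.yml` file.
#' @return a `study_config`.
#' @export
read_study_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      abort("the yaml package is needed for YAML configs")
    yaml::read_yaml(path)
  } else jsonlite::read_json(path, simplifyVector = FALSE)
  flat <- function(x) if (is.list(x)) unlist(x) else x    # scalars & arrays
  sim <- if (!is.null(cfg$sim)) {
    args <- cfg$sim
    markers <- lapply(args$markers, function(mk) do.call(marker_spec, mk))
    args$markers <- NULL
    tp <- args$true_peaks
    args$true_peaks <- NULL
    args <- lapply(args, flat)
    if (identical(flat(cfg$platform), "seldi")) {
      if (!is.null(tp))
        args$true_peaks <- as.data.frame(lapply(
          do.call(Map, c(list(c), tp)), unlist))
      do.call(seldi_sim_config, args)
    } else do.call(dige_sim_config, c(args, list(markers = markers)))
  } else NULL
  comps <- if (!is.null(cfg$comparisons)) {
    lapply(cfg$comparisons, function(cp)
      comparison(flat(cp$name),
                 cells(flat(cp$left$doses), flat(cp$left$days)),
                 cells(flat(cp$right$doses), flat(cp$right$days))))
  } else NULL
  study_config(platform = flat(cfg$platform) %||% "dige", sim = sim,
               days = flat(cfg$days) %||% c(3L, 7L), comparisons = comps,
               selection_method = flat(cfg$selection_method) %||% "plsda",
               eval_method = flat(cfg$eval_method) %||% "lda",
               alpha = flat(cfg$alpha) %||% 0.05,
               n_perm = flat(cfg$n_perm) %||% 9999L,
               train_frac = flat(cfg$train_frac) %||% 0.70,
               master_seed = flat(cfg$master_seed) %||% 1L)
}

# comparison-side class labels for the non-QC samples involved; the treated
# ("left") side is the positive (second) level
comparison_labels <- function(m, comp) {
  idx <- comparison_rows(m, comp)
  rows <- c(idx$right, idx$left)
  list(rows = rows,
       labels = factor(rep(c("right", "left"),
                           c(length(idx$right), length(idx$left))),
                       levels = c("right", "left")))
}

#' Run the full marker-discovery pipeline
#'
#' simulate -> (preprocess, SELDI only) -> univariate statistics ->
#' stability selection -> panel evaluation, for every declared comparison.
#' All randomness derives from `config$master_seed`; re-running an identical
#' config reproduces byte-identical outputs (hashes in the manifest).  Stage
#' boundaries are logged with feature and sample counts so the candidate
#' funnel (all spots -> ANOVA union -> selected panels) is auditable.
#'
#' @param config a [study_config()].
#' @param out_dir output directory; created if needed.
#' @param quiet suppress stage logging (default FALSE).
#' @return a `run_manifest`: config hash, per-stage seeds, output paths with
#'   md5 checksums, per-comparison summaries, wall time.
#' @export
run_pipeline <- function(config, out_dir, quiet = FALSE) {
  stopifnot(inherits(config, "study_config"))
  t0 <- Sys.time()
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(fmt, ...) if (!quiet) message(sprintf(fmt, ...))
  seed <- config$master_seed

  # --- stage 1: simulate -----------------------------------------------
  sim <- config$sim
  sim$seed <- derive_seed(seed, "sim")
  if (config$platform == "dige") {
    parts <- lapply(config$days, function(d) generate_dige_dataset(sim, d))
    m <- labeled_matrix(do.call(rbind, lapply(parts, function(x) x$values)),
                        parts[[1]]$feature_ids,
                        do.call(rbind, lapply(parts, function(x) x$meta)))
  } else {
    parts <- lapply(config$days, function(d) generate_seldi_spectra(sim, d))
    say("preprocess: %d spectra per day", length(parts[[1]]$spectra))
    mats <- lapply(parts, function(pp) seldi_preprocess(pp$spectra)$matrix)
    common <- Reduce(intersect, lapply(mats, function(x) x$feature_ids))
    m <- labeled_matrix(do.call(rbind, lapply(mats, function(x)
      x$values[, common, drop = FALSE])), common,
      do.call(rbind, lapply(mats, function(x) x$meta)))
    m <- drop_qc(m)
    m$values[m$values <= 0] <- min(m$values[m$values > 0]) / 2  # log-safe floor
  }
  say("simulate: %d samples x %d features", nrow(m$values), ncol(m$values))
  write_labeled_matrix(m, file.path(out_dir, "matrix.tsv"))

  # --- stages 2-4 per comparison ---------------------------------------
  summaries <- list()
  for (comp in config$comparisons) {
    cl <- comparison_labels(m, comp)
    sub <- lm_subset(m, samples = cl$rows)
    say("[%s] %d vs %d samples", comp$name, sum(cl$labels == "left"),
        sum(cl$labels == "right"))

    stats_tb <- run_univariate(m, list(comp), n_perm = config$n_perm,
                               seed = derive_seed(seed, "univariate"))
    utils::write.table(stats_tb[[1]],
                       file.path(out_dir, sprintf("stats_%s.tsv", comp$name)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    n_hits <- sum(stats_tb[[1]]$p_anova < config$alpha)
    say("[%s] univariate: %d features at p < %.2f", comp$name, n_hits,
        config$alpha)

    # evaluation split first: selection and panel fitting must never read
    # the held-out rows, so the test AUC stays honest
    split_seed <- derive_seed(seed, "split", comp$name)
    tr <- with_seed(split_seed, stratified_split(cl$labels, config$train_frac))
    te <- setdiff(seq_along(cl$labels), tr)
    sub_tr <- lm_subset(sub, tr)

    sels <- list()
    if ("plsda" %in% config$selection_method) {
      pp <- config$pls_params
      pp$seed <- derive_seed(seed, "select-plsda", comp$name)
      sels$plsda <- plsda_stability_select(sub_tr, cl$labels[tr], pp)
    }
    if ("rf" %in% config$selection_method) {
      rp <- config$rf_params
      rp$seed <- derive_seed(seed, "select-rf", comp$name)
      sels$rf <- rf_stability_select(sub_tr, cl$labels[tr], rp)
    }
    selected <- unique(unlist(lapply(sels, `[[`, "selected"), use.names = FALSE))
    for (nm in names(sels))
      write_selection(sels[[nm]],
                      file.path(out_dir, sprintf("selection_%s_%s.json", nm, comp$name)),
                      file.path(out_dir, sprintf("freq_%s_%s.tsv", nm, comp$name)))
    say("[%s] selection: %d stable feature(s)", comp$name, length(selected))

    report <- evaluate_panel(sub_tr, lm_subset(sub, te),
                             cl$labels[tr], cl$labels[te],
                             candidates = selected, method = config$eval_method)
    write_eval_report(report,
                      file.path(out_dir, sprintf("eval_%s.json", comp$name)),
                      roc_tsv = file.path(out_dir, sprintf("roc_%s.tsv", comp$name)),
                      pca_tsv = file.path(out_dir, sprintf("pca_%s.tsv", comp$name)))
    if (!is.null(report$auc))
      say("[%s] panel %s: test AUC %.3f", comp$name,
          paste(report$panel$variables, collapse = "/"), report$auc[["test"]])

    summaries[[comp$name]] <- list(
      n_anova_hits = n_hits, selected = selected,
      panel = if (!is.null(report$panel)) report$panel$variables,
      auc = report$auc,
      accuracy = c(train = report$confusion$train$accuracy,
                   test = report$confusion$test$accuracy))
  }

  # candidate funnel: union of ANOVA hits and of selected features
  stats_files <- file.path(out_dir, sprintf("stats_%s.tsv",
                                            names(summaries)))
  anova_union <- unique(unlist(lapply(stats_files, function(f) {
    tb <- utils::read.table(f, sep = "\t", header = TRUE)
    tb$feature_id[tb$p_anova < config$alpha]
  })))
  selected_union <- unique(unlist(lapply(summaries, `[[`, "selected")))
  say("funnel: %d features -> %d ANOVA union -> %d with selection",
      ncol(m$values), length(anova_union),
      length(union(anova_union, selected_union)))

  files <- list.files(out_dir, full.names = TRUE)
  manifest <- structure(list(
    config_hash = config_hash(config),
    master_seed = seed,
    n_features = ncol(m$values),
    anova_union_size = length(anova_union),
    candidate_union_size = length(union(anova_union, selected_union)),
    summaries = summaries,
    files = stats::setNames(as.character(tools::md5sum(files)),
                            basename(files)),
    wall_time_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))),
    class = "run_manifest")
  jsonlite::write_json(unclass(manifest)[setdiff(names(manifest), "files")],
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  manifest
}

# stable hash of a config: md5 of its deterministic JSON serialization
config_hash <- function(config) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  jsonlite::write_json(rapply(unclass(config), unclass, how = "replace"),
                       f, auto_unbox = TRUE, digits = NA, force = TRUE)
  as.character(tools::md5sum(f))
}

#' @export
print.run_manifest <- function(x, ...) {
  cat(sprintf("run_manifest: %d comparisons, %d features, %.1f s\n",
              length(x$summaries), x$n_features, x$wall_time_s))
  cat(sprintf("  ANOVA union %d, with selection %d\n",
              x$anova_union_size, x$candidate_union_size))
  for (nm in names(x$summaries)) {
    s <- x$summaries[[nm]]
    cat(sprintf("  %-20s panel %-30s test AUC %s\n", nm,
                paste(s$panel, collapse = "/"),
                if (is.null(s$auc)) "NA" else sprintf("%.3f", s$auc[["test"]])))
  }
  invisible(x)
}
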