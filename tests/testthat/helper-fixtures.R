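# shared fixtures: all built in code, sized for speed

tiny_dige <- function(n_features = 50, seed = 1, markers = list(), ...) {
  dige_sim_config(n_features = n_features, markers = markers, seed = seed, ...)
}

# the standard triage comparison at day 3
comp_ni_ir_d3 <- function() {
  comparison("NI_vs_IR_d3", left = cells(c(20, 40, 80), 3), right = cells(0, 3))
}

# labeled matrix straight from a values matrix (one day, one dose per group
# label is not needed: callers pass an explicit grouping)
lm_from_values <- function(values, doses = NULL, days = 3L) {
  n <- nrow(values)
  if (is.null(doses)) doses <- rep(0, n)
  labeled_matrix(values, sprintf("f%03d", seq_len(ncol(values))),
                 data.frame(sample_id = sprintf("s%03d", seq_len(n)),
                            dose_gy = doses, day = days, batch = 1L,
                            is_qc_pool = FALSE))
}

# one Gaussian bump on a uniform grid
gaussian_spectrum <- function(mz_min = 1000, mz_max = 5000, n = 4001,
                              center = 3000, amp = 100, sigma = 5,
                              offset = 0, noise_sd = 0, seed = 1) {
  set.seed(seed)
  mz <- seq(mz_min, mz_max, length.out = n)
  data.frame(mz = mz,
             intensity = offset + amp * exp(-((mz - center)^2) / (2 * sigma^2)) +
               rnorm(n, 0, noise_sd))
}

# hand-built peak lists for clustering tests: df(sample, mz, intensity, snr)
peaklists_from_table <- function(tab, n_samples) {
  out <- lapply(seq_len(n_samples), function(i) {
    sub <- tab[tab$sample == i, c("mz", "intensity", "snr"), drop = FALSE]
    rownames(sub) <- NULL
    sub
  })
  names(out) <- sprintf("s%03d", seq_len(n_samples))
  out
}
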