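# Shared fixtures, built in code at test time.

# Case-1 simulation scaled down for test speed (the generator's scientific
# defaults are exercised separately).
small_case1_config <- function(seed = 11, spectra_per_subject = 30,
                               n_per_class = 10, ...) {
  sim_config(
    n_subjects_per_class = c(lung_cancer = n_per_class, control = n_per_class),
    spectra_per_subject = spectra_per_subject, seed = seed, ...
  )
}

# Same peaks, every class effect forced to 1 (null hypothesis).
null_peaks <- function() {
  lapply(default_peaks(), function(pk) {
    pk$class_effect[] <- 1
    class(pk) <- "peak_spec"
    pk
  })
}

# Peaks with a single injected effect at one band.
single_effect_peaks <- function(center = 1002, effect = 1.5) {
  lapply(default_peaks(), function(pk) {
    pk$class_effect[] <- if (pk$center == center) {
      c(lung_cancer = effect, other_cancer = 1, control = 1)[names(pk$class_effect)]
    } else 1
    class(pk) <- "peak_spec"
    pk
  })
}

# Membership of grid points in a union of closed intervals.
grid_in_bands <- function(grid, start, end) {
  out <- rep(FALSE, length(grid))
  for (i in seq_along(start)) out <- out | (grid >= start[i] & grid <= end[i])
  out
}

# Jaccard index between recovered VIP bands and ground-truth intervals
# dilated by `edge_tol` cm^-1 on each side, over grid points.
band_jaccard <- function(grid, recovered, truth, edge_tol = 5) {
  rec <- grid_in_bands(grid, recovered$start_cm1, recovered$end_cm1)
  tru <- grid_in_bands(grid, truth$start_cm1 - edge_tol,
                       truth$end_cm1 + edge_tol)
  sum(rec & tru) / sum(rec | tru)
}

# Brute-force Savitzky-Golay oracle: per-position least-squares polynomial
# fit over the centered window, terminal windows at the edges.
sg_brute_force <- function(y, window, polyorder) {
  h <- (window - 1) / 2
  n <- length(y)
  out <- numeric(n)
  for (i in seq_len(n)) {
    c0 <- min(max(i, h + 1), n - h)
    idx <- (c0 - h):(c0 + h)
    fit <- stats::lm(y[idx] ~ stats::poly(idx, polyorder, raw = TRUE))
    out[i] <- unname(stats::predict(fit, newdata = data.frame(idx = i)))
  }
  out
}

# Rank-statistic AUC oracle: tie-corrected Mann-Whitney U / (n1 * n0).
mann_whitney_auc <- function(scores, labels) {
  r <- rank(scores)
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# End-to-end preprocessed small case-1 dataset, cached per session.
cached_case1 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      ds <- generate_dataset(small_case1_config())
      pp <- preprocess_pipeline(ds)
      cache <<- list(raw = ds, preprocessed = pp)
    }
    cache
  }
})

write_spectrum_file <- function(path, wavenumber, intensity, sep = ",",
                                comment = TRUE) {
  lines <- paste(wavenumber, intensity, sep = sep)
  if (comment) lines <- c("# instrument export", lines)
  writeLines(lines, path)
  path
}
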