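#' Preprocessing configuration
#'
#' Tunable parameters of the spectral preprocessing chain. Defaults are the
#' package's standard settings for biofluid SERS: a stiff baseline
#' (`asls_lambda = 1e5`) with strong asymmetry (`asls_p = 0.01`) so the fit
#' hugs the lower envelope under the Raman bands, an 11-point cubic
#' Savitzky-Golay smoother, and the 735-1700 cm^-1 fingerprint crop used for
#' chemometrics.
#'
#' @param asls_lambda Baseline smoothness weight (> 0).
#' @param asls_p Baseline asymmetry, in (0, 0.5): weight given to points
#'   above the current baseline estimate.
#' @param asls_max_iter,asls_tol Reweighting iteration cap and relative
#'   weight-change stopping tolerance.
#' @param sg_window Savitzky-Golay window length (odd, >= 5).
#' @param sg_polyorder Savitzky-Golay polynomial order (< `sg_window`).
#' @param despike_threshold Modified z-score threshold for cosmic-ray bins.
#' @param crop_range Fingerprint interval kept for analysis, cm^-1 (closed).
#' @param normalize `"mean"` (divide each spectrum by its mean intensity) or
#'   `"none"`.
#' @return A `preprocess_config` list.
#' @export
preprocess_config <- function(asls_lambda = 1e5, asls_p = 0.01,
                              asls_max_iter = 15, asls_tol = 1e-6,
                              sg_window = 11, sg_polyorder = 3,
                              despike_threshold = 8,
                              crop_range = c(735, 1700),
                              normalize = c("mean", "none")) {
  normalize <- match.arg(normalize)
  stopifnot(asls_lambda > 0, asls_p > 0, asls_p < 0.5, asls_max_iter >= 1,
            sg_window %% 2 == 1, sg_window >= 5, sg_polyorder < sg_window,
            length(crop_range) == 2, crop_range[1] < crop_range[2])
  structure(list(
    asls_lambda = asls_lambda, asls_p = asls_p,
    asls_max_iter = as.integer(asls_max_iter), asls_tol = asls_tol,
    sg_window = as.integer(sg_window), sg_polyorder = as.integer(sg_polyorder),
    despike_threshold = despike_threshold,
    crop_range = crop_range, normalize = normalize
  ), class = "preprocess_config")
}

# Banded solve with two steps of mixed-precision iterative refinement: the
# penalized system is ill-conditioned (kappa ~ lambda / p), and refinement
# with an extended-precision residual recovers the digits lost to that
# conditioning.
solve_penalized <- function(d0, d1, d2, b) {
  z <- pentadiag_solve(d0, d1, d2, b)
  for (i in 1:2) {
    r <- pentadiag_residual(d0, d1, d2, z, b)
    z <- z + pentadiag_solve(d0, d1, d2, r)
  }
  z
}

# Bands of the second-difference penalty matrix D'D (D the (n-2) x n second
# difference operator): main diagonal (1,5,6,...,6,5,1), first off-diagonal
# (-2,-4,...,-4,-2), second off-diagonal all 1.
dtd_bands <- function(n) {
  list(
    d0 = c(1, 5, rep(6, n - 4), 5, 1),
    d1 = c(-2, rep(-4, n - 3), -2),
    d2 = rep(1, n - 2)
  )
}

#' Asymmetric least squares baseline estimation
#'
#' Estimates the smooth autofluorescence background under a Raman spectrum as
#' the minimizer of `sum_i w_i (y_i - z_i)^2 + lambda * sum (Delta^2 z)^2`,
#' iterating the asymmetric reweighting `w_i <- p` if `y_i > z_i` else
#' `1 - p` from an all-ones start until the weights stop changing, their
#' relative change drops below `tol`, or `max_iter` is reached. With small
#' `p`, points above the baseline (the Raman bands) barely pull the fit up,
#' so the estimate tracks the lower envelope. Each iteration solves the
#' banded (pentadiagonal) penalized system exactly.
#'
#' @param intensities Finite numeric vector, length >= 8.
#' @param lambda Smoothness weight (> 0); larger values give stiffer
#'   baselines.
#' @param p Asymmetry parameter in (0, 0.5).
#' @param max_iter,tol Iteration cap and relative weight-change tolerance.
#' @return The baseline vector, same length as the input.
#' @export
#' @examples
#' y <- 100 + 0.5 * (1:200) + 500 / (1 + ((1:200) - 100)^2 / 36)
#' b <- asls_baseline(y)
asls_baseline <- function(intensities, lambda = 1e5, p = 0.01,
                          max_iter = 15, tol = 1e-6) {
  assert_finite_numeric(intensities, "intensities")
  n <- length(intensities)
  if (n < 8) abort("asls_baseline needs at least 8 points")
  if (lambda <= 0) abort("lambda must be positive")
  if (p <= 0 || p >= 0.5) abort("p must lie strictly in (0, 0.5)")
  bands <- dtd_bands(n)
  # The objective is affine-equivariant (the second-difference penalty
  # annihilates affine functions and the asymmetric weights depend only on
  # residual signs), so the input is detrended and rescaled first: this
  # removes the large-magnitude component that the conditioning of the
  # penalized system (kappa ~ lambda / p) would otherwise multiply into
  # roundoff, and makes the fit exact on affine inputs.
  idx <- seq_len(n)
  slope <- stats::cov(idx, intensities) / stats::var(idx)
  trend <- mean(intensities) + slope * (idx - mean(idx))
  resid <- intensities - trend
  scale <- max(abs(resid), 1e-300)
  y <- resid / scale
  w <- rep(1, n)
  z <- y
  for (iter in seq_len(max_iter)) {
    z <- solve_penalized(w + lambda * bands$d0, lambda * bands$d1,
                         lambda * bands$d2, w * y)
    w_new <- ifelse(y > z, p, 1 - p)
    if (identical(w_new, w) || sum(abs(w_new - w)) / sum(w) < tol) {
      w <- w_new
      break
    }
    w <- w_new
  }
  z * scale + trend
}

#' Savitzky-Golay smoothing
#'
#' Replaces each point by the value of the least-squares polynomial of order
#' `polyorder` fitted over the centered window of length `window`. The first
#' and last half-windows are handled by evaluating the polynomial fitted to
#' the terminal windows at the edge positions, so polynomials of degree at
#' most `polyorder` are reproduced exactly everywhere, edges included.
#'
#' @param intensities Finite numeric vector, at least `window` long.
#' @param window Odd window length.
#' @param polyorder Polynomial order, `< window`.
#' @return Smoothed vector.
#' @export
savgol_smooth <- function(intensities, window = 11, polyorder = 3) {
  assert_finite_numeric(intensities, "intensities")
  if (window %% 2 != 1) abort("window must be odd")
  if (window > length(intensities)) abort("window longer than the spectrum")
  if (polyorder >= window) abort("polyorder must be smaller than window")
  as.numeric(signal::sgolayfilt(intensities, p = polyorder, n = window))
}

#' Remove single-bin cosmic-ray spikes
#'
#' Cosmic rays hit single detector bins and so produce extreme second
#' differences. Bins whose modified z-score (median/MAD-based) of the second
#' difference exceeds `z_threshold` in magnitude are replaced by linear
#' interpolation of the surrounding clean bins. If more than 5% of bins are
#' flagged the input is not spike-contaminated but pathological, and an
#' error is raised rather than silently rewriting the spectrum.
#'
#' @param intensities Finite numeric vector, length >= 8.
#' @param z_threshold Modified z-score cutoff (default 8).
#' @return Despiked vector.
#' @export
despike <- function(intensities, z_threshold = 8) {
  assert_finite_numeric(intensities, "intensities")
  n <- length(intensities)
  if (n < 8) abort("despike needs at least 8 points")
  d <- diff(intensities, differences = 2)
  med <- median(d)
  mad_raw <- median(abs(d - med))
  if (mad_raw == 0) {
    mz <- ifelse(d == med, 0, Inf)
  } else {
    mz <- 0.6745 * (d - med) / mad_raw
  }
  flagged <- rep(FALSE, n)
  flagged[seq(2, n - 1)] <- abs(mz) > z_threshold
  if (!any(flagged)) return(intensities)
  if (mean(flagged) > 0.05) {
    abort(sprintf(
      "%.1f%% of bins flagged as spikes (limit 5%%): input looks pathological, not spiked",
      100 * mean(flagged)))
  }
  clean <- which(!flagged)
  out <- intensities
  out[flagged] <- approx(clean, intensities[clean], xout = which(flagged),
                         rule = 2)$y
  out
}

#' Crop a dataset to a wavenumber interval
#'
#' Restricts the grid and intensity columns to the closed interval
#' `[range[1], range[2]]`, by default the 735-1700 cm^-1 fingerprint region
#' used for chemometric analysis.
#'
#' @param dataset A [spectral_dataset()].
#' @param range Length-2 numeric, cm^-1.
#' @return The cropped [spectral_dataset()].
#' @export
crop <- function(dataset, range = c(735, 1700)) {
  stopifnot(inherits(dataset, "spectral_dataset"), length(range) == 2)
  keep <- dataset$grid >= range[1] & dataset$grid <= range[2]
  if (!any(keep)) {
    abort(sprintf("no grid points in [%.1f, %.1f]", range[1], range[2]))
  }
  out <- spectral_dataset(dataset$grid[keep],
                          dataset$intensities[, keep, drop = FALSE],
                          dataset$meta)
  attr(out, "truth") <- attr(dataset, "truth")
  out
}

#' Per-spectrum mean normalization
#'
#' Divides each spectrum by its own mean intensity over the current grid, so
#' every row mean becomes 1. Removes per-acquisition intensity scale
#' (laser power, focus, substrate enhancement) while preserving relative
#' band heights.
#'
#' @param dataset A [spectral_dataset()].
#' @return The normalized [spectral_dataset()].
#' @export
normalize_mean <- function(dataset) {
  stopifnot(inherits(dataset, "spectral_dataset"))
  m <- rowMeans(dataset$intensities)
  if (any(m <= 0)) {
    abort(sprintf("%d spectra have non-positive mean intensity; cannot mean-normalize",
                  sum(m <= 0)))
  }
  out <- spectral_dataset(dataset$grid, dataset$intensities / m, dataset$meta)
  attr(out, "truth") <- attr(dataset, "truth")
  out
}

#' Column mean-centering
#'
#' Subtracts the per-wavenumber mean across spectra, returning both the
#' centered dataset and the removed mean vector so held-out data can be
#' centered with training means (see [cross_validate()], which applies
#' centering inside folds only).
#'
#' @param dataset A [spectral_dataset()] with at least 2 spectra.
#' @return List with elements `dataset` (centered) and `center` (the column
#'   mean vector).
#' @export
mean_center <- function(dataset) {
  stopifnot(inherits(dataset, "spectral_dataset"))
  if (nrow(dataset$intensities) < 2) abort("mean-centering needs >= 2 spectra")
  ctr <- colMeans(dataset$intensities)
  out <- spectral_dataset(dataset$grid,
                          sweep(dataset$intensities, 2, ctr, `-`),
                          dataset$meta)
  attr(out, "truth") <- attr(dataset, "truth")
  list(dataset = out, center = ctr)
}

#' Run the full spectral preprocessing chain
#'
#' Applies, per spectrum: despiking, subtraction of the asymmetric
#' least-squares baseline, and Savitzky-Golay smoothing; then crops the
#' dataset to the fingerprint range and (optionally) mean-normalizes each
#' spectrum. Despiking precedes the baseline fit so cosmic-ray bins cannot
#' distort it. Column mean-centering is deliberately *not* part of this
#' chain: it is applied on training folds only during cross-validation.
#'
#' @param dataset A [spectral_dataset()].
#' @param config A [preprocess_config()].
#' @return The preprocessed [spectral_dataset()].
#' @export
preprocess_pipeline <- function(dataset, config = preprocess_config()) {
  stopifnot(inherits(dataset, "spectral_dataset"),
            inherits(config, "preprocess_config"))
  if (nrow(dataset$intensities) == 0) abort("empty dataset")
  x <- dataset$intensities
  for (i in seq_len(nrow(x))) {
    y <- despike(x[i, ], z_threshold = config$despike_threshold)
    y <- y - asls_baseline(y, lambda = config$asls_lambda, p = config$asls_p,
                           max_iter = config$asls_max_iter,
                           tol = config$asls_tol)
    x[i, ] <- savgol_smooth(y, window = config$sg_window,
                            polyorder = config$sg_polyorder)
  }
  out <- spectral_dataset(dataset$grid, x, dataset$meta)
  attr(out, "truth") <- attr(dataset, "truth")
  out <- crop(out, config$crop_range)
  if (config$normalize == "mean") out <- normalize_mean(out)
  out
}
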