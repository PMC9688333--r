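#' Variable importance in projection (VIP) scores
#'
#' Wold's VIP: for wavenumber `j`,
#' `VIP_j = sqrt( p * sum_a SS_a w_aj^2 / sum_a SS_a )`, where
#' `SS_a = q_a^2 (t_a' t_a)` is the response sum of squares explained by
#' latent variable `a` and the weight columns are unit-norm. The mean of the
#' squared scores is exactly 1, so wavenumbers with VIP above 1 contribute
#' more than an average variable to the discrimination — the standard
#' selection rule for discriminative Raman bands.
#'
#' @param model A fitted [fit_plsda()] model (training scores retained).
#' @param threshold Importance cutoff for band extraction (default 1).
#' @param min_width Minimum band width in cm^-1 passed to
#'   [extract_vip_bands()].
#' @return A `vip_result`: tibble of per-wavenumber scores plus the maximal
#'   contiguous bands exceeding the threshold.
#' @export
vip_scores <- function(model, threshold = 1, min_width = 1) {
  stopifnot(inherits(model, "plsda"))
  if (is.null(model$T)) abort("model has no stored training scores")
  ss <- (model$q^2) * colSums(model$T^2)
  vip <- sqrt(model$p * as.vector(model$W^2 %*% ss) / sum(ss))
  wn <- model$grid %||% seq_len(model$p)
  scores <- tibble::tibble(wavenumber = wn, vip = vip)
  structure(list(
    scores = scores,
    bands = extract_vip_bands(scores, threshold = threshold,
                              min_width = min_width),
    threshold = threshold
  ), class = "vip_result")
}

#' @export
print.vip_result <- function(x, ...) {
  cat(sprintf("<vip_result> %d wavenumbers, %d band(s) with VIP > %g\n",
              nrow(x$scores), nrow(x$bands), x$threshold))
  if (nrow(x$bands) > 0) print(x$bands)
  invisible(x)
}

#' @export
tidy.vip_result <- function(x, ...) x$scores

#' @export
glance.vip_result <- function(x, ...) {
  tibble::tibble(
    n_wavenumbers = nrow(x$scores),
    n_bands = nrow(x$bands),
    max_vip = max(x$scores$vip),
    mean_vip_sq = mean(x$scores$vip^2)
  )
}

#' Extract contiguous discriminative bands from VIP scores
#'
#' Maximal runs of consecutive grid points with VIP above the threshold,
#' reported as closed wavenumber intervals at grid resolution. Runs narrower
#' than `min_width` (interval length counting one grid spacing per point)
#' are discarded.
#'
#' @param scores A `vip_result` or a data frame with `wavenumber` and `vip`
#'   columns on a contiguous grid.
#' @param threshold Score cutoff (default 1).
#' @param min_width Minimum band width, cm^-1.
#' @return Tibble with `start_cm1`, `end_cm1`, `peak_cm1` (position of the
#'   maximum score in the band) and `max_vip`.
#' @export
extract_vip_bands <- function(scores, threshold = 1, min_width = 1) {
  if (inherits(scores, "vip_result")) scores <- scores$scores
  scores <- tibble::as_tibble(scores)
  stopifnot(all(c("wavenumber", "vip") %in% names(scores)))
  wn <- scores$wavenumber
  spacing <- if (length(wn) > 1) median(diff(wn)) else 1
  runs <- runs_of(scores$vip > threshold)
  if (nrow(runs) == 0) {
    return(tibble::tibble(start_cm1 = double(), end_cm1 = double(),
                          peak_cm1 = double(), max_vip = double()))
  }
  out <- purrr::pmap_dfr(runs, function(start, end) {
    seg <- scores[start:end, ]
    tibble::tibble(
      start_cm1 = wn[start], end_cm1 = wn[end],
      peak_cm1 = seg$wavenumber[which.max(seg$vip)],
      max_vip = max(seg$vip)
    )
  })
  dplyr::filter(out, (.data$end_cm1 - .data$start_cm1) + spacing >= min_width)
}

#' Class mean spectra and their difference
#'
#' Per-wavenumber mean of the (preprocessed) spectra of two classes and
#' their difference `a - b` — the difference spectrum plotted alongside VIP
#' scores when reading which bands separate the groups.
#'
#' @param dataset A [spectral_dataset()].
#' @param class_a,class_b Class labels present in the dataset.
#' @return Tibble with `wavenumber`, `mean_a`, `mean_b`, `difference`.
#' @export
group_mean_difference <- function(dataset, class_a = "lung_cancer",
                                  class_b = "control") {
  stopifnot(inherits(dataset, "spectral_dataset"))
  for (cl in c(class_a, class_b)) {
    if (!any(dataset$meta$class_label == cl, na.rm = TRUE)) {
      abort(sprintf("class '%s' not present in the dataset", cl))
    }
  }
  ma <- colMeans(dataset$intensities[dataset$meta$class_label %in% class_a, ,
                                     drop = FALSE])
  mb <- colMeans(dataset$intensities[dataset$meta$class_label %in% class_b, ,
                                     drop = FALSE])
  tibble::tibble(wavenumber = dataset$grid, mean_a = ma, mean_b = mb,
                 difference = ma - mb)
}
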