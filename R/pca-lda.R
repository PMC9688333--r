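#' PCA-LDA comparator classifier
#'
#' The classical chemometric baseline: project spectra onto the leading
#' principal components of the training data, then apply a two-class Fisher
#' linear discriminant to the projected scores, thresholding at the midpoint
#' of the projected class means. Included as a comparator for PLS-DA, which
#' rotates its latent variables toward class separation rather than variance.
#'
#' @param x_train Raw training matrix (spectra in rows).
#' @param y_train 0/1 vector (1 = case); both classes required.
#' @param x_test Matrix to classify, same columns as `x_train`.
#' @param n_pcs Number of principal components retained,
#'   `<= min(nrow - 1, ncol)`.
#' @return A `pca_lda` list: `prediction` tibble (`score`,
#'   `predicted_class`) for `x_test`, `pc_variance` (variance of the
#'   training data along each retained component), and the discriminant
#'   threshold.
#' @export
pca_lda_classify <- function(x_train, y_train, x_test, n_pcs = 2) {
  x_train <- as.matrix(x_train)
  x_test <- as.matrix(x_test)
  y_train <- as.numeric(y_train)
  if (length(unique(y_train)) < 2) abort("training labels contain a single class")
  if (n_pcs > min(nrow(x_train) - 1, ncol(x_train))) {
    abort("n_pcs exceeds the achievable rank of the training data")
  }
  mu <- colMeans(x_train)
  xc <- sweep(x_train, 2, mu, `-`)
  sv <- svd(xc, nu = 0, nv = n_pcs)
  rot <- sv$v
  s_train <- xc %*% rot
  s_test <- sweep(x_test, 2, mu, `-`) %*% rot
  # Fisher direction on PC scores: pooled within-class covariance.
  s0 <- s_train[y_train == 0, , drop = FALSE]
  s1 <- s_train[y_train == 1, , drop = FALSE]
  sw <- (crossprod(scale(s0, scale = FALSE)) +
           crossprod(scale(s1, scale = FALSE))) /
    (nrow(s_train) - 2)
  dmean <- colMeans(s1) - colMeans(s0)
  d <- tryCatch(solve(sw, dmean), error = function(e) dmean)
  proj_train <- as.vector(s_train %*% d)
  m0 <- mean(proj_train[y_train == 0])
  m1 <- mean(proj_train[y_train == 1])
  thr <- (m0 + m1) / 2
  proj_test <- as.vector(s_test %*% d)
  side <- sign(m1 - m0)
  structure(list(
    prediction = tibble::tibble(
      score = proj_test,
      predicted_class = as.integer(side * (proj_test - thr) >= 0)
    ),
    pc_variance = (sv$d[seq_len(n_pcs)]^2) / (nrow(x_train) - 1),
    threshold = thr,
    n_pcs = n_pcs
  ), class = "pca_lda")
}
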