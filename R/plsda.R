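#' Fit a PLS-DA binary classifier
#'
#' Partial least squares discriminant analysis: PLS1 regression of a 0/1
#' class response on the column-centered descriptor matrix, fitted by
#' NIPALS. For each latent variable `a`, the weight vector is
#' `w_a = X'y_c / ||X'y_c||` (`y_c` the centered response), scores
#' `t_a = X w_a`, X-loadings `p_a = X't_a / (t_a't_a)`, Y-loading
#' `q_a = y_c't_a / (t_a't_a)`, after which X is deflated by `t_a p_a'` and
#' `y_c` by `q_a t_a`. Each latent variable thus maximizes covariance with
#' the class coding among directions orthogonal (in score space) to the
#' previous ones.
#'
#' @param x Column-centered numeric matrix, spectra in rows (see
#'   [mean_center()]).
#' @param y Numeric 0/1 vector (1 = case); both classes must be present.
#' @param ncomp Number of latent variables, `<= min(nrow(x) - 1, ncol(x))`.
#' @param x_mean Optional centering vector removed from `x`, stored for
#'   prediction on raw data.
#' @param grid Optional wavenumber axis (cm^-1) for the columns of `x`, used
#'   by [vip_scores()] to report bands in physical units.
#' @return A `plsda` model: weights `W` (unit-norm columns), X-loadings `P`,
#'   Y-loadings `q`, training scores `T`, `y_mean`, `x_mean`, and the
#'   decision threshold 0.5.
#' @seealso [predict_plsda()], [vip_scores()], [cross_validate()]
#' @export
fit_plsda <- function(x, y, ncomp = 2, x_mean = NULL, grid = NULL) {
  x <- as.matrix(x)
  y <- as.numeric(y)
  n <- nrow(x)
  p <- ncol(x)
  if (length(y) != n) abort("length(y) must equal nrow(x)")
  if (!all(y %in% c(0, 1))) abort("y must be coded 0/1")
  if (length(unique(y)) < 2) abort("y contains a single class; cannot fit a discriminant")
  if (ncomp < 1 || ncomp > min(n - 1, p)) {
    abort(sprintf("ncomp must be in 1..min(n-1, p) = %d", min(n - 1, p)))
  }
  col_mu <- colMeans(x)
  if (max(abs(col_mu)) > 1e-6 * max(1, max(abs(x)))) {
    abort("x must be column-centered (see mean_center())")
  }
  y_mean <- mean(y)
  yc <- y - y_mean
  W <- matrix(0, p, ncomp)
  P <- matrix(0, p, ncomp)
  Tm <- matrix(0, n, ncomp)
  q <- numeric(ncomp)
  scale0 <- sqrt(sum(crossprod(x, yc)^2))
  for (a in seq_len(ncomp)) {
    w <- crossprod(x, yc)
    nw <- sqrt(sum(w^2))
    if (nw <= 1e-12 * max(scale0, 1)) {
      abort(sprintf("x/y covariance exhausted: achievable rank is %d, requested %d",
                    a - 1, ncomp))
    }
    w <- w / nw
    t_a <- as.vector(x %*% w)
    tt <- sum(t_a^2)
    if (tt <= .Machine$double.eps * n) {
      abort(sprintf("descriptor rank exhausted: achievable rank is %d, requested %d",
                    a - 1, ncomp))
    }
    p_a <- as.vector(crossprod(x, t_a)) / tt
    q_a <- sum(yc * t_a) / tt
    x <- x - tcrossprod(t_a, p_a)
    yc <- yc - q_a * t_a
    W[, a] <- w
    P[, a] <- p_a
    Tm[, a] <- t_a
    q[a] <- q_a
  }
  structure(list(
    ncomp = ncomp, W = W, P = P, q = q, T = Tm, y = y,
    y_mean = y_mean, x_mean = x_mean, grid = grid,
    n = n, p = p, decision_threshold = 0.5
  ), class = "plsda")
}

#' @export
print.plsda <- function(x, ...) {
  cat(sprintf("<plsda> %d latent variable(s), %d spectra x %d wavenumbers\n",
              x$ncomp, x$n, x$p))
  invisible(x)
}

# Regression coefficients implied by the first `a` latent variables:
# B = W_a (P_a' W_a)^{-1} q_a, mapping centered X to centered y.
plsda_coef <- function(model, ncomp = model$ncomp) {
  a <- seq_len(ncomp)
  Wa <- model$W[, a, drop = FALSE]
  Pa <- model$P[, a, drop = FALSE]
  as.vector(Wa %*% solve(crossprod(Pa, Wa), model$q[a]))
}

#' Predict class membership from a PLS-DA model
#'
#' Centers the new spectra with the training column means, applies the PLS
#' regression coefficients, and adds back the training response mean. The
#' continuous score estimates class membership on the 0/1 coding scale;
#' spectra with score at or above the 0.5 threshold are labelled as cases.
#'
#' @param model A fitted [fit_plsda()] model.
#' @param x_new Raw (uncentered) matrix with the same columns as training.
#' @param x_mean Centering vector; defaults to the one stored in the model.
#' @param ncomp Number of latent variables to use (default: all fitted).
#' @return Tibble with `score` (continuous) and `predicted_class` (0/1).
#' @export
predict_plsda <- function(model, x_new, x_mean = model$x_mean,
                          ncomp = model$ncomp) {
  stopifnot(inherits(model, "plsda"))
  x_new <- as.matrix(x_new)
  if (ncol(x_new) != model$p) {
    abort(sprintf("x_new has %d columns; model expects %d", ncol(x_new), model$p))
  }
  if (is.null(x_mean)) x_mean <- rep(0, model$p)
  b <- plsda_coef(model, ncomp)
  score <- as.vector(sweep(x_new, 2, x_mean, `-`) %*% b) + model$y_mean
  tibble::tibble(
    score = score,
    predicted_class = as.integer(score >= model$decision_threshold)
  )
}

#' @export
tidy.plsda <- function(x, ...) {
  p <- x$p
  wn <- x$grid %||% seq_len(p)
  tibble::tibble(
    wavenumber = rep(wn, times = x$ncomp),
    component = rep(seq_len(x$ncomp), each = p),
    weight = as.vector(x$W),
    loading = as.vector(x$P)
  )
}

#' @export
glance.plsda <- function(x, ...) {
  fitted <- as.vector(x$T %*% x$q) + x$y_mean
  y <- NULL
  ss_expl <- sum((x$q^2) * colSums(x$T^2))
  tibble::tibble(
    n = x$n, p = x$p, ncomp = x$ncomp,
    ss_response_explained = ss_expl
  )
}

#' Latent-variable scores of a fitted model
#'
#' @param model A [fit_plsda()] model.
#' @return Tibble with one row per training spectrum: `lv1`, `lv2`, ... score
#'   columns.
#' @export
plsda_scores <- function(model) {
  stopifnot(inherits(model, "plsda"))
  s <- as.data.frame(model$T)
  names(s) <- paste0("lv", seq_len(model$ncomp))
  tibble::as_tibble(s)
}
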