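test_that("the first weight vector concentrates on an informative column", {
  set.seed(5)
  n <- 40
  y <- rep(c(0, 1), n / 2)
  yc <- y - mean(y)
  # one column proportional to the centered response; nine noise columns
  # orthogonalized against it
  noise <- matrix(rnorm(n * 9), n, 9)
  noise <- noise - yc %*% t(crossprod(noise, yc)) / sum(yc^2)
  x <- cbind(2 * yc, noise)
  x <- scale(x, scale = FALSE)
  m <- fit_plsda(x, y, ncomp = 1)
  expect_gt(m$W[1, 1]^2, 0.9)
})

test_that("full-rank PLS equals the least-squares projection of the response", {
  set.seed(6)
  x <- scale(matrix(rnorm(6 * 3), 6, 3), scale = FALSE)
  y <- c(0, 1, 0, 1, 1, 0)
  m <- fit_plsda(x, y, ncomp = 3)
  fitted <- predict_plsda(m, x, x_mean = rep(0, 3))$score
  oracle <- as.vector(x %*% solve(crossprod(x), crossprod(x, y - mean(y)))) +
    mean(y)
  expect_lt(max(abs(fitted - oracle)), 1e-8)
})

test_that("NIPALS scores are orthogonal and weights unit-norm", {
  set.seed(7)
  x <- scale(matrix(rnorm(20 * 50), 20, 50), scale = FALSE)
  y <- rep(c(0, 1), 10)
  m <- fit_plsda(x, y, ncomp = 6)
  g <- crossprod(m$T)
  expect_lt(max(abs(g - diag(diag(g)))), 1e-8)
  expect_lt(max(abs(colSums(m$W^2) - 1)), 1e-10)
  # residual X-scores have zero covariance with the residual response
  xr <- x
  yr <- y - mean(y)
  for (a in seq_len(m$ncomp)) {
    xr <- xr - tcrossprod(m$T[, a], m$P[, a])
    yr <- yr - m$q[a] * m$T[, a]
  }
  expect_lt(max(abs(crossprod(xr %*% m$W, yr))), 1e-8)
})

test_that("fit matches the reference PLS implementation on small instances", {
  skip_if_not_installed("mixOmics")
  set.seed(8)
  for (rep in 1:3) {
    n <- sample(8:12, 1)
    p <- sample(4:12, 1)
    x <- scale(matrix(rnorm(n * p), n, p), scale = FALSE)
    colnames(x) <- paste0("v", seq_len(p))
    y <- rep_len(c(0, 1), n)
    a <- sample(1:3, 1)
    ref <- mixOmics::pls(x, y, ncomp = a, scale = FALSE, mode = "regression")
    ref_fit <- predict(ref, x)$predict[, , a]
    m <- fit_plsda(x, y, ncomp = a)
    ours <- predict_plsda(m, x, x_mean = rep(0, p))$score
    expect_lt(max(abs(ours - ref_fit)), 1e-6)
  }
})

test_that("fitting validates response coding, centering, and rank", {
  x <- scale(matrix(rnorm(30), 10, 3), scale = FALSE)
  expect_error(fit_plsda(x, rep(1, 10), 1), "single class")
  expect_error(fit_plsda(x, rep_len(c(1, 2), 10), 1), "0/1")
  expect_error(fit_plsda(x + 5, rep_len(c(0, 1), 10), 1), "centered")
  expect_error(fit_plsda(x, rep_len(c(0, 1), 10), 9), "ncomp")
  # rank-deficient X: asking past the achievable rank names it
  xr <- scale(cbind(rnorm(10)) %*% rbind(rnorm(4)), scale = FALSE)
  expect_error(fit_plsda(xr, rep_len(c(0, 1), 10), 3), "rank is 1")
})

test_that("prediction is consistent in-sample, constant on the mean, and monotone", {
  set.seed(9)
  x <- matrix(rnorm(20 * 8, 50), 20, 8)
  y <- rep_len(c(0, 1), 20)
  ctr <- colMeans(x)
  m <- fit_plsda(sweep(x, 2, ctr, `-`), y, ncomp = 2, x_mean = ctr)
  # training rows give the in-sample fitted values
  fitted <- as.vector(m$T %*% m$q) + m$y_mean
  expect_equal(predict_plsda(m, x)$score, fitted, tolerance = 1e-10)
  # rows at the training mean score at the response mean
  at_mean <- matrix(ctr, 3, 8, byrow = TRUE)
  expect_equal(predict_plsda(m, at_mean)$score, rep(m$y_mean, 3),
               tolerance = 1e-10)
  # adding the positive-response direction raises the score
  b <- serschemo:::plsda_coef(m)
  step <- predict_plsda(m, sweep(at_mean, 2, 0.1 * b / sqrt(sum(b^2)), `+`))
  expect_true(all(step$score > m$y_mean))
  expect_error(predict_plsda(m, x[, 1:5]), "columns")
})

test_that("VIP scores satisfy their algebraic identities", {
  set.seed(10)
  x <- scale(matrix(rnorm(20 * 8), 20, 8), scale = FALSE)
  y <- rep_len(c(0, 1), 20)
  m <- fit_plsda(x, y, ncomp = 2)
  v <- vip_scores(m)
  expect_lt(abs(mean(v$scores$vip^2) - 1), 1e-8)
  expect_lt(abs(sum(v$scores$vip^2) - m$p), 1e-6)
  # scalar-loop oracle of the SS-weighted formula
  ss <- numeric(m$ncomp)
  for (a in seq_len(m$ncomp)) ss[a] <- m$q[a]^2 * sum(m$T[, a]^2)
  oracle <- numeric(m$p)
  for (j in seq_len(m$p)) {
    acc <- 0
    for (a in seq_len(m$ncomp)) {
      acc <- acc + ss[a] * (m$W[j, a] / sqrt(sum(m$W[, a]^2)))^2
    }
    oracle[j] <- sqrt(m$p * acc / sum(ss))
  }
  expect_lt(max(abs(v$scores$vip - oracle)), 1e-10)
  # single component, equal |weights|: every VIP is exactly 1
  w <- rep(1 / sqrt(4), 4)
  m1 <- list(ncomp = 1, W = matrix(w), q = 2, T = matrix(rnorm(10)),
             p = 4, grid = NULL)
  class(m1) <- "plsda"
  expect_equal(vip_scores(m1)$scores$vip, rep(1, 4), tolerance = 1e-12)
})

test_that("VIP matches the reference implementation", {
  skip_if_not_installed("mixOmics")
  set.seed(11)
  x <- scale(matrix(rnorm(16 * 9), 16, 9), scale = FALSE)
  colnames(x) <- paste0("v", 1:9)
  y <- rep_len(c(0, 1), 16)
  m <- fit_plsda(x, y, ncomp = 2)
  ref <- mixOmics::pls(x, y, ncomp = 2, scale = FALSE, mode = "regression")
  expect_lt(max(abs(vip_scores(m)$scores$vip - mixOmics::vip(ref)[, 2])), 1e-6)
})

test_that("band extraction returns maximal runs above threshold", {
  grid <- 995:1020
  vip <- rep(0.5, length(grid))
  scores <- tibble::tibble(wavenumber = grid, vip = vip)
  expect_equal(nrow(extract_vip_bands(scores)), 0)
  vip[grid >= 1000 & grid <= 1010] <- 1.5
  scores$vip <- vip
  bands <- extract_vip_bands(scores)
  expect_equal(nrow(bands), 1)
  expect_equal(c(bands$start_cm1, bands$end_cm1), c(1000, 1010))
  # a second, sub-minimum-width run is dropped
  vip[grid == 1018] <- 1.2
  scores$vip <- vip
  expect_equal(nrow(extract_vip_bands(scores, min_width = 2)), 1)
  expect_equal(nrow(extract_vip_bands(scores, min_width = 1)), 2)
})

test_that("group mean difference is antisymmetric and peaks at the injected band", {
  cfg <- small_case1_config(spectra_per_subject = 2, n_per_class = 2,
                            noise_sd = 0, spike_rate = 0, subject_sd = 0,
                            baseline_amplitude = 0,
                            peaks = single_effect_peaks(1002, 1.5))
  ds <- generate_dataset(cfg)
  d1 <- group_mean_difference(ds, "lung_cancer", "control")
  d2 <- group_mean_difference(ds, "control", "lung_cancer")
  expect_equal(d1$difference, -d2$difference)
  expect_equal(d1$wavenumber[which.max(abs(d1$difference))], 1002)
  # identical classes give a null difference
  ctrl_row <- which(ds$meta$class_label == "control")[1]
  same <- spectral_dataset(ds$grid, ds$intensities[c(1, 1, 1, 1), ],
                           ds$meta[c(1, 1, ctrl_row, ctrl_row), ])
  expect_equal(max(abs(group_mean_difference(same, "lung_cancer",
                                             "control")$difference)), 0)
  expect_error(group_mean_difference(ds, "other_cancer", "control"),
               "not present")
})

test_that("PCA-LDA separates separable clouds and is at chance under permuted labels", {
  set.seed(12)
  n <- 100
  y <- rep_len(c(0, 1), n)
  x <- matrix(rnorm(n * 5), n, 5)
  x[y == 1, 1] <- x[y == 1, 1] + 10
  split <- rep_len(c(TRUE, TRUE, FALSE, FALSE), n)
  fit <- pca_lda_classify(x[split, ], y[split], x[!split, ], n_pcs = 2)
  expect_equal(mean(fit$prediction$predicted_class == y[!split]), 1.0)
  # training variance along PCs equals the covariance eigenvalues
  ev <- eigen(stats::cov(x[split, ]), symmetric = TRUE)$values[1:2]
  expect_lt(max(abs(fit$pc_variance - ev)), 1e-8)
  # permuted labels: accuracy near chance
  acc <- replicate(20, {
    yp <- sample(y[split])
    f <- pca_lda_classify(x[split, ], yp, x[!split, ], n_pcs = 2)
    mean(f$prediction$predicted_class == y[!split])
  })
  expect_lt(abs(mean(acc) - 0.5), 0.15)
  expect_error(pca_lda_classify(x[split, ], rep(1, sum(split)), x[!split, ]),
               "single class")
})

test_that("tidiers expose model structure as tibbles", {
  set.seed(13)
  x <- scale(matrix(rnorm(20 * 6), 20, 6), scale = FALSE)
  y <- rep_len(c(0, 1), 20)
  m <- fit_plsda(x, y, ncomp = 2, grid = 100 + 1:6)
  td <- tidy(m)
  expect_equal(nrow(td), 12)
  expect_named(td, c("wavenumber", "component", "weight", "loading"))
  gl <- glance(m)
  expect_equal(gl$ncomp, 2)
  sc <- plsda_scores(m)
  expect_named(sc, c("lv1", "lv2"))
  expect_equal(nrow(sc), 20)
})
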