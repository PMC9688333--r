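test_that("fold assignment stratifies subjects and is reproducible", {
  subj <- sprintf("s%02d", 1:20)
  cls <- rep(c("case", "control"), each = 10)
  plan <- make_folds(subj, cls, k = 10, seed = 3)
  by_fold <- dplyr::count(plan$assignments, fold, class_label)
  # exact divisibility: one case and one control per fold
  expect_true(all(by_fold$n == 1))
  expect_equal(sort(unique(plan$assignments$fold)), 1:10)
  # same seed, same plan; different seed, different shuffle
  expect_identical(make_folds(subj, cls, k = 10, seed = 3)$assignments,
                   plan$assignments)
  expect_false(identical(make_folds(subj, cls, k = 10, seed = 4)$assignments,
                         plan$assignments))
  # proportions within one subject of global for uneven classes
  plan2 <- make_folds(sprintf("t%02d", 1:23),
                      rep(c("case", "control"), c(12, 11)), k = 10, seed = 1)
  tab <- table(plan2$assignments$fold, plan2$assignments$class_label)
  expect_true(all(tab >= 1 - 1e-9 | tab == 0))
  expect_true(max(tab[, "case"]) - min(tab[, "case"]) <= 1)
  expect_true(max(tab[, "control"]) - min(tab[, "control"]) <= 1)
  expect_error(make_folds(sprintf("u%d", 1:5), rep(c("a", "b"), c(3, 2)),
                          k = 10), "smaller k")
})

test_that("ROC/AUC equals the Mann-Whitney rank statistic on random instances", {
  set.seed(14)
  for (i in 1:100) {
    n <- sample(10:60, 1)
    labels <- rbinom(n, 1, 0.5)
    if (length(unique(labels)) < 2) labels[1:2] <- c(0, 1)
    scores <- rnorm(n) + labels * runif(1, 0, 2)
    if (i %% 3 == 0) scores <- round(scores, 1) # force ties
    expect_lt(abs(roc_auc(scores, labels)$auc -
                    mann_whitney_auc(scores, labels)), 1e-10)
  }
})

test_that("ROC endpoints, separability, and score negation behave canonically", {
  scores <- c(0.1, 0.2, 0.8, 0.9)
  labels <- c(0, 0, 1, 1)
  r <- roc_auc(scores, labels)
  expect_equal(r$auc, 1.0)
  expect_equal(r$roc$fpr[1], 0)
  expect_equal(r$roc$tpr[1], 0)
  expect_equal(tail(r$roc$fpr, 1), 1)
  expect_equal(tail(r$roc$tpr, 1), 1)
  set.seed(15)
  s <- rnorm(50)
  l <- rbinom(50, 1, 0.5)
  l[1:2] <- c(0, 1)
  expect_equal(roc_auc(-s, l)$auc, 1 - roc_auc(s, l)$auc, tolerance = 1e-12)
  expect_error(roc_auc(s, rep(1, 50)), "both classes")
})

test_that("vertical ROC averaging is idempotent and averages AUC arithmetically", {
  r <- roc_auc(c(0.1, 0.4, 0.6, 0.9), c(0, 1, 0, 1))
  avg <- average_roc(list(r$roc, r$roc))
  interp <- approx(r$roc$fpr, r$roc$tpr, xout = avg$roc$fpr, ties = max)$y
  expect_equal(avg$roc$tpr, interp)
  expect_equal(avg$mean_auc, r$auc)
  # perfect + chance folds
  perfect <- roc_auc(c(1, 2, 3, 4), c(0, 0, 1, 1))
  chance <- roc_auc(c(1, 2, 3, 4), c(1, 0, 0, 1))
  two <- average_roc(list(perfect$roc, chance$roc),
                     aucs = c(perfect$auc, chance$auc))
  expect_equal(two$mean_auc, 0.75)
  # trapezoid area of the averaged curve tracks the mean of fold areas
  set.seed(16)
  rocs <- lapply(1:5, function(i) {
    s <- rnorm(200) + rbinom(200, 1, 0.5)
    l <- as.numeric(s > median(s) + rnorm(200, 0, 0.5))
    if (length(unique(l)) < 2) l[1:2] <- c(0, 1)
    roc_auc(s, l)
  })
  avg2 <- average_roc(lapply(rocs, `[[`, "roc"))
  area <- sum(diff(avg2$roc$fpr) *
                (head(avg2$roc$tpr, -1) + tail(avg2$roc$tpr, -1)) / 2)
  expect_lt(abs(area - mean(vapply(rocs, `[[`, 0, "auc"))), 0.02)
  expect_error(average_roc(list()), "no ROC")
})

test_that("cross-validation is perfect on strongly separated noise-free classes", {
  cfg <- small_case1_config(spectra_per_subject = 4, n_per_class = 6,
                            noise_sd = 0.5, spike_rate = 0, subject_sd = 0.02,
                            peaks = single_effect_peaks(1002, 3))
  pp <- preprocess_pipeline(generate_dataset(cfg))
  cv <- cross_validate(pp, k = 6, seed = 2, ncomp = 2)
  expect_equal(glance(cv)$mean_accuracy, 1.0)
  expect_equal(glance(cv)$mean_auc, 1.0)
  expect_equal(glance(cv)$mean_sensitivity, 1.0)
  expect_equal(glance(cv)$mean_specificity, 1.0)
})

test_that("per-fold confusion counts add up and metrics are order invariant", {
  cfg <- small_case1_config(spectra_per_subject = 4, n_per_class = 6)
  pp <- preprocess_pipeline(generate_dataset(cfg))
  cv <- cross_validate(pp, k = 3, seed = 5, ncomp = 2)
  expect_equal(cv$folds$tp + cv$folds$fp + cv$folds$tn + cv$folds$fn,
               cv$folds$n_units)
  expect_true(all(cv$folds$accuracy >= 0 & cv$folds$accuracy <= 1))
  # permuting the spectrum order leaves the report unchanged
  perm <- withr::with_seed(1, sample(nrow(pp$intensities)))
  shuffled <- filter_spectra(pp, perm)
  cv2 <- cross_validate(shuffled, fold_plan = cv$fold_plan, ncomp = 2)
  expect_equal(cv2$folds, cv$folds)
  expect_equal(glance(cv2), glance(cv))
})

test_that("subject-permuted labels drop performance to chance", {
  cfg <- small_case1_config(spectra_per_subject = 4, n_per_class = 8, seed = 6)
  pp <- preprocess_pipeline(generate_dataset(cfg))
  accs <- vapply(1:5, function(s) {
    subjects <- unique(pp$meta$subject_id)
    relabel <- withr::with_seed(s, setNames(sample(
      pp$meta$class_label[match(subjects, pp$meta$subject_id)]), subjects))
    meta2 <- pp$meta
    meta2$class_label <- unname(relabel[meta2$subject_id])
    ds2 <- spectral_dataset(pp$grid, pp$intensities, meta2)
    cv <- cross_validate(ds2, k = 4, seed = s, ncomp = 2)
    glance(cv)$mean_accuracy
  }, 0)
  expect_lt(abs(mean(accs) - 0.5), 0.2)
})

test_that("spectrum-level evaluation is available behind the level flag", {
  cfg <- small_case1_config(spectra_per_subject = 4, n_per_class = 6)
  pp <- preprocess_pipeline(generate_dataset(cfg))
  cv <- cross_validate(pp, k = 3, seed = 7, ncomp = 2, level = "spectrum")
  expect_equal(sum(cv$folds$n_units), nrow(pp$intensities))
  expect_equal(cv$summary$level, "spectrum")
})

test_that("a fold plan that mismatches the dataset or leaves one class fails loudly", {
  cfg <- small_case1_config(spectra_per_subject = 3, n_per_class = 4)
  pp <- preprocess_pipeline(generate_dataset(cfg))
  other <- make_folds(sprintf("x%d", 1:8), rep(c("case", "control"), 4), k = 4)
  expect_error(cross_validate(pp, fold_plan = other, ncomp = 2),
               "do not match")
  # all case subjects in one test fold leaves single-class training folds
  bad_plan <- make_folds(pp$meta$subject_id,
                         ifelse(pp$meta$class_label == "lung_cancer",
                                "case", "control"), k = 4, seed = 1)
  bad_plan$assignments$fold <- ifelse(bad_plan$assignments$class_label == "case",
                                      1L, 2L)
  expect_error(cross_validate(pp, fold_plan = bad_plan, ncomp = 2),
               "single class")
})

test_that("inner model-size selection picks a usable small model", {
  cfg <- small_case1_config(spectra_per_subject = 4, n_per_class = 8)
  pp <- preprocess_pipeline(generate_dataset(cfg))
  cv <- cross_validate(pp, k = 4, seed = 8, ncomp_max = 4)
  expect_true(all(cv$folds$ncomp >= 1 & cv$folds$ncomp <= 4))
  expect_gt(glance(cv)$mean_auc, 0.8)
})
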