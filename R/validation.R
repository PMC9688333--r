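#' Subject-stratified fold assignment
#'
#' Deals *subjects* (never individual spectra) into `k` folds: within each
#' class, subjects are shuffled under the seed and assigned round-robin, so
#' per-fold class counts differ from exact proportionality by at most one
#' subject. All mapping spectra of a subject travel with its fold — the
#' guard against a classifier recognizing a subject rather than a disease.
#'
#' @param subject_ids Character vector, one entry per spectrum (or per
#'   subject; duplicates are collapsed).
#' @param class_labels Class label per entry; must be constant within
#'   subject.
#' @param k Number of folds (default 10).
#' @param seed Integer seed controlling the shuffle.
#' @return A `fold_plan`: tibble of `subject_id`, `class_label`, `fold`
#'   (1..k), with `k` and `seed` attached.
#' @export
make_folds <- function(subject_ids, class_labels, k = 10, seed = 1L) {
  subjects <- tibble::tibble(subject_id = as.character(subject_ids),
                             class_label = as.character(class_labels)) |>
    dplyr::distinct()
  if (anyDuplicated(subjects$subject_id)) {
    abort("a subject maps to more than one class label")
  }
  if (nrow(subjects) < k) {
    abort(sprintf("only %d subjects for %d folds; use a smaller k",
                  nrow(subjects), k))
  }
  counts <- table(subjects$class_label)
  if (length(counts) < 2 || any(counts < 2)) {
    abort("need at least 2 subjects in each of at least 2 classes")
  }
  assignments <- withr::with_seed(as.integer(seed), {
    subjects |>
      dplyr::group_by(.data$class_label) |>
      dplyr::slice_sample(prop = 1) |>
      dplyr::mutate(fold = ((dplyr::row_number() - 1L) %% k) + 1L) |>
      dplyr::ungroup() |>
      dplyr::arrange(.data$subject_id)
  })
  structure(list(assignments = assignments, k = as.integer(k),
                 seed = as.integer(seed)),
            class = "fold_plan")
}

#' @export
print.fold_plan <- function(x, ...) {
  cat(sprintf("<fold_plan> %d subjects in %d folds (seed %d)\n",
              nrow(x$assignments), x$k, x$seed))
  invisible(x)
}

#' ROC curve and area under the curve
#'
#' Sweeps every distinct score value as a decision threshold (predict case
#' when `score >= threshold`), yielding one ROC point per threshold plus the
#' (0,0) endpoint; tied scores step TPR and FPR simultaneously, producing the
#' conventional diagonal segment. AUC is the trapezoid-rule area, which
#' under this tie handling equals the tie-corrected Mann-Whitney statistic
#' `U / (n1 * n0)`.
#'
#' @param scores Continuous classifier scores.
#' @param labels 0/1 vector; both classes must be present.
#' @return List with `roc` (tibble `threshold`, `fpr`, `tpr`) and `auc`.
#' @export
roc_auc <- function(scores, labels) {
  scores <- as.numeric(scores)
  labels <- as.numeric(labels)
  stopifnot(length(scores) == length(labels), all(labels %in% c(0, 1)))
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) abort("both classes must be present to compute a ROC curve")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  l <- labels[ord]
  tp <- cumsum(l)
  fp <- cumsum(1 - l)
  last_of_tie <- c(diff(s) != 0, TRUE)
  roc <- tibble::tibble(
    threshold = c(Inf, s[last_of_tie]),
    fpr = c(0, fp[last_of_tie] / n0),
    tpr = c(0, tp[last_of_tie] / n1)
  )
  auc <- sum(diff(roc$fpr) * (head(roc$tpr, -1) + tail(roc$tpr, -1)) / 2)
  list(roc = roc, auc = auc)
}

#' Vertically average ROC curves across folds
#'
#' Interpolates each fold's TPR on a fixed FPR grid (0 to 1 in steps of
#' 0.01 by default) and averages point-wise; the summary AUC is the
#' arithmetic mean of the per-fold AUCs.
#'
#' @param rocs List of ROC point tibbles (from [roc_auc()]).
#' @param aucs Optional per-fold AUCs; recomputed by trapezoid rule when
#'   omitted.
#' @param fpr_grid FPR grid for vertical averaging.
#' @return List with `roc` (tibble `fpr`, `tpr`) and `mean_auc`.
#' @export
average_roc <- function(rocs, aucs = NULL, fpr_grid = seq(0, 1, 0.01)) {
  if (length(rocs) == 0) abort("no ROC curves to average")
  tprs <- vapply(rocs, function(r) {
    approx(r$fpr, r$tpr, xout = fpr_grid, ties = max, rule = 2)$y
  }, numeric(length(fpr_grid)))
  if (is.null(aucs)) {
    aucs <- vapply(rocs, function(r) {
      sum(diff(r$fpr) * (head(r$tpr, -1) + tail(r$tpr, -1)) / 2)
    }, 0)
  }
  list(
    roc = tibble::tibble(fpr = fpr_grid, tpr = rowMeans(tprs)),
    mean_auc = mean(aucs)
  )
}

confusion_metrics <- function(predicted, truth) {
  tp <- sum(predicted == 1 & truth == 1)
  fp <- sum(predicted == 1 & truth == 0)
  tn <- sum(predicted == 0 & truth == 0)
  fn <- sum(predicted == 0 & truth == 1)
  tibble::tibble(
    tp = tp, fp = fp, tn = tn, fn = fn,
    accuracy = (tp + tn) / (tp + fp + tn + fn),
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_
  )
}

# Pick the number of latent variables by inner subject-stratified
# cross-validation on the training block, maximizing spectrum-level
# accuracy; ties go to the smallest model.
select_ncomp <- function(x, y, subject_ids, ncomp_max = 10, inner_k = 5,
                         seed = 1L) {
  subjects <- tibble::tibble(subject_id = subject_ids, y = y) |>
    dplyr::distinct()
  k <- min(inner_k, min(table(subjects$y)))
  a_max <- min(ncomp_max, nrow(x) - 1, ncol(x))
  if (k < 2) return(min(2L, a_max))
  plan <- make_folds(subjects$subject_id, as.character(subjects$y),
                     k = k, seed = seed)
  correct <- matrix(0, nrow = k, ncol = a_max)
  total <- numeric(k)
  for (f in seq_len(k)) {
    test_sub <- plan$assignments$subject_id[plan$assignments$fold == f]
    in_test <- subject_ids %in% test_sub
    if (length(unique(y[!in_test])) < 2) return(min(2L, a_max))
    ctr <- colMeans(x[!in_test, , drop = FALSE])
    xc <- sweep(x[!in_test, , drop = FALSE], 2, ctr, `-`)
    a_fit <- min(a_max, sum(!in_test) - 1)
    model <- tryCatch(fit_plsda(xc, y[!in_test], ncomp = a_fit),
                      error = function(e) NULL)
    if (is.null(model)) return(min(2L, a_max))
    xt <- sweep(x[in_test, , drop = FALSE], 2, ctr, `-`)
    for (a in seq_len(a_max)) {
      pred <- predict_plsda(model, xt, x_mean = rep(0, ncol(x)),
                            ncomp = min(a, model$ncomp))
      correct[f, a] <- sum(pred$predicted_class == y[in_test])
    }
    total[f] <- sum(in_test)
  }
  acc <- colSums(correct) / sum(total)
  which.max(acc) # first maximum = smallest model among ties
}

#' Subject-stratified k-fold cross-validation of PLS-DA
#'
#' The evaluation loop: for each fold, the training spectra are column
#' mean-centered (the means are carried to the held-out fold, never computed
#' on it), a PLS-DA model is fitted — with the number of latent variables
#' chosen by inner cross-validation unless fixed via `ncomp` — and the
#' held-out spectra are scored. Scores are aggregated to the evaluation
#' level (`"subject"`: mean continuous score over a subject's spectra,
#' the default; `"spectrum"`: each spectrum counted separately), thresholded
#' at 0.5 for confusion metrics, and swept for a per-fold ROC curve. A
#' leakage guard asserts on every run that no subject contributes spectra to
#' both sides of any fold.
#'
#' @param dataset A preprocessed [spectral_dataset()] (despiked,
#'   baseline-corrected, smoothed, cropped, normalized — see
#'   [preprocess_pipeline()]).
#' @param case_labels Class labels forming the positive (case) group.
#' @param control_labels Labels forming the negative group.
#' @param fold_plan A [make_folds()] plan; built from `k` and `seed` when
#'   omitted.
#' @param k,seed Fold count and seed used when `fold_plan` is `NULL`.
#' @param ncomp Fixed number of latent variables, or `NULL` to select by
#'   inner cross-validation (1..`ncomp_max`, ties to the smallest).
#' @param ncomp_max Largest model considered by the inner selection.
#' @param level `"subject"` or `"spectrum"` evaluation.
#' @return A `cv_report`: per-fold confusion metrics and AUC, per-fold ROC
#'   points, the vertically averaged ROC, pooled predictions, and aggregate
#'   means. Access with [tidy()] (per fold) and [glance()] (aggregate).
#' @export
cross_validate <- function(dataset, case_labels = "lung_cancer",
                           control_labels = "control",
                           fold_plan = NULL, k = 10, seed = 1L,
                           ncomp = NULL, ncomp_max = 10,
                           level = c("subject", "spectrum")) {
  stopifnot(inherits(dataset, "spectral_dataset"))
  level <- match.arg(level)
  meta <- dataset$meta
  known <- meta$class_label %in% c(case_labels, control_labels)
  if (!all(known)) {
    abort(paste0("dataset contains classes outside the case/control grouping: ",
                 paste(unique(meta$class_label[!known]), collapse = ", ")))
  }
  y <- as.numeric(meta$class_label %in% case_labels)
  if (is.null(fold_plan)) {
    fold_plan <- make_folds(meta$subject_id,
                            ifelse(y == 1, "case", "control"),
                            k = k, seed = seed)
  }
  stopifnot(inherits(fold_plan, "fold_plan"))
  assign <- fold_plan$assignments
  if (!setequal(assign$subject_id, meta$subject_id)) {
    abort("fold plan subjects do not match the dataset")
  }
  x <- dataset$intensities
  folds <- list()
  rocs <- list()
  preds <- list()
  for (f in sort(unique(assign$fold))) {
    test_sub <- assign$subject_id[assign$fold == f]
    in_test <- meta$subject_id %in% test_sub
    # Leakage guard: a subject must never sit on both sides of a fold.
    if (length(intersect(meta$subject_id[in_test], meta$subject_id[!in_test])) > 0) {
      abort("leakage: a subject appears in both training and test of a fold")
    }
    if (length(unique(y[!in_test])) < 2) {
      abort(sprintf("fold %d leaves a single class in training", f))
    }
    ctr <- colMeans(x[!in_test, , drop = FALSE])
    xc <- sweep(x[!in_test, , drop = FALSE], 2, ctr, `-`)
    a <- ncomp %||% select_ncomp(xc, y[!in_test], meta$subject_id[!in_test],
                                 ncomp_max = ncomp_max,
                                 seed = stage_seed(fold_plan$seed, paste0("inner", f)))
    a <- min(a, sum(!in_test) - 1, ncol(x))
    model <- fit_plsda(xc, y[!in_test], ncomp = a, grid = dataset$grid)
    xt <- sweep(x[in_test, , drop = FALSE], 2, ctr, `-`)
    pred <- predict_plsda(model, xt, x_mean = rep(0, ncol(x)))
    unit <- tibble::tibble(
      fold = f,
      subject_id = meta$subject_id[in_test],
      truth = y[in_test],
      score = pred$score
    )
    if (level == "subject") {
      unit <- unit |>
        dplyr::group_by(.data$fold, .data$subject_id) |>
        dplyr::summarise(truth = .data$truth[1], score = mean(.data$score),
                         .groups = "drop")
    }
    unit$predicted_class <- as.integer(unit$score >= 0.5)
    cm <- confusion_metrics(unit$predicted_class, unit$truth)
    if (length(unique(unit$truth)) == 2) {
      ra <- roc_auc(unit$score, unit$truth)
      rocs[[length(rocs) + 1]] <- ra$roc
      auc_f <- ra$auc
    } else {
      auc_f <- NA_real_
    }
    folds[[f]] <- dplyr::bind_cols(
      tibble::tibble(fold = f, n_units = nrow(unit), ncomp = a), cm,
      tibble::tibble(auc = auc_f))
    preds[[f]] <- unit
  }
  fold_tab <- dplyr::bind_rows(folds)
  avg <- average_roc(rocs, aucs = fold_tab$auc[!is.na(fold_tab$auc)])
  structure(list(
    folds = fold_tab,
    rocs = rocs,
    mean_roc = avg$roc,
    predictions = dplyr::bind_rows(preds),
    summary = tibble::tibble(
      level = level,
      k = fold_plan$k,
      mean_accuracy = mean(fold_tab$accuracy),
      mean_sensitivity = mean(fold_tab$sensitivity, na.rm = TRUE),
      mean_specificity = mean(fold_tab$specificity, na.rm = TRUE),
      mean_auc = avg$mean_auc
    ),
    level = level,
    fold_plan = fold_plan
  ), class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "<cv_report> %d-fold CV at %s level: accuracy %.3f, sensitivity %.3f, specificity %.3f, mean AUC %.3f\n",
    s$k, s$level, s$mean_accuracy, s$mean_sensitivity, s$mean_specificity,
    s$mean_auc))
  invisible(x)
}

#' @export
tidy.cv_report <- function(x, ...) x$folds

#' @export
glance.cv_report <- function(x, ...) x$summary
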