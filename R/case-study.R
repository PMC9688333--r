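#' Apply a case-study grouping to subject metadata
#'
#' The two diagnostic questions the pipeline answers: `"lung_vs_control"`
#' compares lung-cancer subjects against non-cancer controls, *excluding*
#' other cancers entirely; `"all_cancer_vs_control"` pools lung and other
#' cancers into one case group against the controls.
#'
#' @param meta Data frame with `subject_id` and `class_label` columns (a
#'   manifest, roster, or `spectral_dataset` metadata).
#' @param case Grouping name.
#' @return The rows retained by the grouping, with a `group` column
#'   (`"case"` / `"control"`) added.
#' @export
#' @examples
#' dplyr::count(assign_case_groups(subject_roster(), "all_cancer_vs_control"),
#'              group)
assign_case_groups <- function(meta,
                               case = c("lung_vs_control",
                                        "all_cancer_vs_control")) {
  case <- match.arg(case)
  meta <- tibble::as_tibble(meta)
  stopifnot(all(c("subject_id", "class_label") %in% names(meta)))
  case_classes <- if (case == "lung_vs_control") "lung_cancer" else
    c("lung_cancer", "other_cancer")
  meta |>
    dplyr::filter(.data$class_label %in% c(case_classes, "control")) |>
    dplyr::mutate(group = ifelse(.data$class_label %in% case_classes,
                                 "case", "control"))
}

case_classes_for <- function(case) {
  if (case == "lung_vs_control") "lung_cancer" else
    c("lung_cancer", "other_cancer")
}

#' Configure an end-to-end case study
#'
#' Bundles the scenario, simulation settings, preprocessing parameters, and
#' cross-validation settings of one full run. When `sim` is omitted, the
#' scenario's default simulation is used: 12 lung-cancer vs 11 control
#' subjects for `"lung_vs_control"`, and the full study roster split
#' (15 lung + 7 other cancers vs 12 controls) for
#' `"all_cancer_vs_control"`, both with the scenario's default band set.
#' All stage seeds (simulation, fold assignment, model selection) are
#' derived from the single `seed`.
#'
#' @inheritParams assign_case_groups
#' @param sim A [sim_config()], or `NULL` for the scenario default.
#' @param preprocess A [preprocess_config()].
#' @param k Cross-validation folds (default 10).
#' @param seed Top-level integer seed.
#' @param output_dir Directory where [run_case_study()] writes its tables.
#' @return A `case_study_config` list.
#' @export
case_study_config <- function(case = c("lung_vs_control",
                                       "all_cancer_vs_control"),
                              sim = NULL,
                              preprocess = preprocess_config(),
                              k = 10, seed = 1L,
                              output_dir = tempfile("case_study_")) {
  case <- match.arg(case)
  if (is.null(sim)) {
    counts <- if (case == "lung_vs_control") {
      c(lung_cancer = 12, control = 11)
    } else {
      c(lung_cancer = 15, other_cancer = 7, control = 12)
    }
    sim <- sim_config(n_subjects_per_class = counts,
                      peaks = default_peaks(case),
                      seed = stage_seed(seed, "simulate"))
  }
  stopifnot(inherits(sim, "sim_config"),
            inherits(preprocess, "preprocess_config"))
  structure(list(case = case, sim = sim, preprocess = preprocess,
                 k = as.integer(k), seed = as.integer(seed),
                 output_dir = output_dir),
            class = "case_study_config")
}

# Delimited output with a provenance header: every table carries the config
# hash and top-level seed.
write_output_table <- function(tab, path, hash, seed) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# config_hash=%s seed=%d", hash, seed), con)
  writeLines(readr::format_csv(tab), con, sep = "")
  invisible(path)
}

#' Run a complete synthetic case study
#'
#' The full pipeline as one call: simulate the SERS mapping dataset, apply
#' the case grouping, preprocess every spectrum, run subject-stratified
#' k-fold cross-validation, fit a final PLS-DA model on the whole
#' (preprocessed, centered) dataset, and score wavenumber importance. All
#' result tables are written to `config$output_dir` as delimited text, each
#' with a header line carrying the configuration hash and seed; the same
#' config and seed reproduce the outputs byte for byte.
#'
#' @param config A [case_study_config()].
#' @param ncomp Fixed number of latent variables, or `NULL` (default) to
#'   select by inner cross-validation.
#' @return A `case_study` result: the preprocessed dataset, `cv`
#'   ([cross_validate()] report), `model`, `vip` ([vip_scores()]),
#'   `mean_difference`, `summary` tibble, and `output_dir`.
#' @export
run_case_study <- function(config, ncomp = NULL) {
  stopifnot(inherits(config, "case_study_config"))
  t0 <- Sys.time()
  log_lines <- character()
  log_stage <- function(msg) {
    line <- sprintf("[%6.1fs] %s", as.numeric(Sys.time() - t0, units = "secs"), msg)
    message(line)
    log_lines <<- c(log_lines, line)
  }
  hash <- rlang::hash(config[c("case", "sim", "preprocess", "k", "seed")])
  case_classes <- case_classes_for(config$case)

  log_stage(sprintf("simulate: %s", config$case))
  raw <- generate_dataset(config$sim)
  keep <- raw$meta$class_label %in% c(case_classes, "control")
  truth <- attr(raw, "truth")
  ds <- filter_spectra(raw, keep)
  attr(ds, "truth") <- truth

  log_stage(sprintf("preprocess: %d spectra", nrow(ds$intensities)))
  ds <- preprocess_pipeline(ds, config$preprocess)

  log_stage("cross-validate")
  plan <- make_folds(ds$meta$subject_id,
                     ifelse(ds$meta$class_label %in% case_classes,
                            "case", "control"),
                     k = config$k, seed = stage_seed(config$seed, "folds"))
  cv <- cross_validate(ds, case_labels = case_classes,
                       fold_plan = plan, ncomp = ncomp)

  log_stage("final fit + VIP")
  centered <- mean_center(ds)
  y <- as.numeric(ds$meta$class_label %in% case_classes)
  a <- ncomp %||% select_ncomp(centered$dataset$intensities, y,
                               ds$meta$subject_id,
                               seed = stage_seed(config$seed, "ncomp"))
  model <- fit_plsda(centered$dataset$intensities, y, ncomp = a,
                     x_mean = centered$center, grid = ds$grid)
  vip <- vip_scores(model)
  mean_diff <- group_mean_difference(centered$dataset,
                                     class_a = case_classes,
                                     class_b = "control")

  summary_tab <- dplyr::bind_cols(
    tibble::tibble(case = config$case, n_case = sum(y), ncomp = a),
    cv$summary,
    tibble::tibble(n_vip_bands = nrow(vip$bands))
  )

  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(name) file.path(config$output_dir, name)
  write_output_table(summary_tab, out("summary.csv"), hash, config$seed)
  write_output_table(cv$folds, out("fold_metrics.csv"), hash, config$seed)
  write_output_table(cv$mean_roc, out("roc_mean.csv"), hash, config$seed)
  write_output_table(
    purrr::imap_dfr(cv$rocs, ~dplyr::mutate(.x, fold = .y)),
    out("roc_folds.csv"), hash, config$seed)
  write_output_table(vip$scores, out("vip_scores.csv"), hash, config$seed)
  write_output_table(vip$bands, out("vip_bands.csv"), hash, config$seed)
  write_output_table(mean_diff, out("mean_difference.csv"), hash, config$seed)
  write_output_table(
    dplyr::bind_cols(ds$meta["subject_id"],
                     tibble::tibble(class_label = ds$meta$class_label),
                     plsda_scores(model)),
    out("lv_scores.csv"), hash, config$seed)
  log_stage("done")
  writeLines(log_lines, out("run.log"))

  structure(list(
    dataset = ds, cv = cv, model = model, vip = vip,
    mean_difference = mean_diff, summary = summary_tab,
    truth = truth, config = config, output_dir = config$output_dir
  ), class = "case_study")
}

#' @export
print.case_study <- function(x, ...) {
  cat(sprintf("<case_study> %s\n", x$config$case))
  print(x$cv)
  cat(sprintf("  VIP bands > 1: %d\n", nrow(x$vip$bands)))
  invisible(x)
}

#' @export
glance.case_study <- function(x, ...) x$summary
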