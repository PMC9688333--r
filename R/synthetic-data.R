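#' Describe one synthetic SERS band
#'
#' A Lorentzian line — the standard Raman band shape — with a class-dependent
#' multiplicative intensity effect. `class_effect` is a named vector of
#' factors (1 = no effect); classes not named default to 1.
#'
#' @param center Band position, cm^-1, inside the acquisition range.
#' @param fwhm Full width at half maximum, cm^-1, in \[4, 60\].
#' @param base_amplitude Peak height in counts for an unaffected class.
#' @param class_effect Named numeric vector of per-class intensity factors.
#' @return A `peak_spec` list.
#' @export
#' @examples
#' peak_spec(1002, class_effect = c(lung_cancer = 1.5))
peak_spec <- function(center, fwhm = 12, base_amplitude = 500,
                      class_effect = c()) {
  stopifnot(fwhm >= 4, fwhm <= 60, base_amplitude >= 0)
  eff <- stats::setNames(rep(1, length(CLASS_LEVELS)), CLASS_LEVELS)
  if (length(class_effect) > 0) {
    bad <- setdiff(names(class_effect), CLASS_LEVELS)
    if (length(bad) > 0) abort(paste0("unknown class in class_effect: ",
                                      paste(bad, collapse = ", ")))
    eff[names(class_effect)] <- class_effect
  }
  structure(list(center = center, fwhm = fwhm,
                 base_amplitude = base_amplitude, class_effect = eff),
            class = "peak_spec")
}

#' Default band sets for the two case-study scenarios
#'
#' `"lung_vs_control"` places Lorentzian bands at the positions assigned to
#' phenylalanine, lipid C-C skeletal, nucleic acid, CH2/CH3 and olefinic
#' modes (1002, 1068, 1168, 1198, 1310, 1398, 1432, 1558, 1590 cm^-1), with
#' lung-cancer intensity factors of 1.3-1.6 on the bands reported as
#' discriminative between lung cancer and control pleural fluid, so that
#' recovery tests have ground truth where a real study found signal.
#' `"all_cancer_vs_control"` adds protein/amide bands (887, 959, 1008, 1078,
#' 1222, 1325, 1655 cm^-1) with effects shared by both cancer classes.
#'
#' @param case Scenario name.
#' @return List of [peak_spec()]s.
#' @export
default_peaks <- function(case = c("lung_vs_control", "all_cancer_vs_control")) {
  case <- match.arg(case)
  lung <- function(f) c(lung_cancer = f)
  both <- function(f) c(lung_cancer = f, other_cancer = f)
  eff <- if (case == "lung_vs_control") lung else both
  base <- list(
    peak_spec(1002, base_amplitude = 600, class_effect = eff(1.5)),
    peak_spec(1068, base_amplitude = 450, class_effect = eff(1.4)),
    peak_spec(1168, base_amplitude = 400, class_effect = eff(1.3)),
    peak_spec(1198, base_amplitude = 380, class_effect = eff(1.3)),
    peak_spec(1310, base_amplitude = 500, class_effect = eff(1.4)),
    peak_spec(1398, base_amplitude = 420, class_effect = eff(1.3)),
    peak_spec(1432, base_amplitude = 480, class_effect = eff(1.4)),
    peak_spec(1558, base_amplitude = 350, class_effect = eff(1.3)),
    peak_spec(1590, base_amplitude = 550, class_effect = eff(1.6))
  )
  if (case == "all_cancer_vs_control") {
    base <- c(base, list(
      peak_spec(887, base_amplitude = 300, class_effect = both(1.3)),
      peak_spec(959, base_amplitude = 320, class_effect = both(1.3)),
      peak_spec(1078, base_amplitude = 350, class_effect = both(1.4)),
      peak_spec(1222, base_amplitude = 400, class_effect = both(1.3)),
      peak_spec(1325, base_amplitude = 380, class_effect = both(1.3)),
      peak_spec(1655, base_amplitude = 500, class_effect = both(1.4))
    ))
  }
  base
}

#' Configure the synthetic SERS study generator
#'
#' Defaults mirror the acquisition protocol the pipeline targets: at least
#' 500 mapping spectra per pleural fluid sample over 3 substrate locations,
#' 700-1800 cm^-1, a broad autofluorescence baseline overlapping the SERS
#' bands, iid detector noise, sparse single-bin cosmic-ray spikes, and a
#' log-normal per-subject SERS enhancement gain.
#'
#' @param n_subjects_per_class Named integer vector (class -> subject count),
#'   or a single integer applied to `lung_cancer` and `control`. Every class
#'   needs at least 2 subjects for cross-validation to be possible.
#' @param spectra_per_subject Mapping spectra per subject (default 500).
#' @param n_locations Mapping locations per sample (default 3).
#' @param peaks List of [peak_spec()]s (default [default_peaks()]).
#' @param baseline_amplitude Height of the autofluorescence baseline, counts.
#' @param noise_sd Detector noise standard deviation, counts.
#' @param spike_rate Expected cosmic-ray spikes per spectrum (Poisson).
#' @param subject_sd Log-scale SD of the subject multiplicative gain.
#' @param seed Integer RNG seed; identical configs give identical datasets.
#' @param grid Wavenumber grid (default [canonical_grid()]).
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_subjects_per_class = c(lung_cancer = 12, control = 11),
                       spectra_per_subject = 500,
                       n_locations = 3,
                       peaks = default_peaks(),
                       baseline_amplitude = 2000,
                       noise_sd = 20,
                       spike_rate = 0.05,
                       subject_sd = 0.15,
                       seed = 1L,
                       grid = canonical_grid()) {
  if (is.null(names(n_subjects_per_class))) {
    stopifnot(length(n_subjects_per_class) == 1)
    n_subjects_per_class <- c(lung_cancer = n_subjects_per_class,
                              control = n_subjects_per_class)
  }
  bad <- setdiff(names(n_subjects_per_class), CLASS_LEVELS)
  if (length(bad) > 0) abort(paste0("unknown class: ", paste(bad, collapse = ", ")))
  stopifnot(
    spectra_per_subject >= 1, n_locations >= 1,
    baseline_amplitude >= 0, noise_sd >= 0, spike_rate >= 0, subject_sd >= 0
  )
  for (pk in peaks) {
    stopifnot(inherits(pk, "peak_spec"))
    if (pk$center < min(grid) || pk$center > max(grid)) {
      abort(sprintf("peak center %.0f cm^-1 outside the grid range", pk$center))
    }
  }
  structure(list(
    n_subjects_per_class = n_subjects_per_class,
    spectra_per_subject = as.integer(spectra_per_subject),
    n_locations = as.integer(n_locations),
    peaks = peaks,
    baseline_amplitude = baseline_amplitude,
    noise_sd = noise_sd,
    spike_rate = spike_rate,
    subject_sd = subject_sd,
    seed = as.integer(seed),
    grid = grid
  ), class = "sim_config")
}

lorentzian <- function(x, center, fwhm, amplitude) {
  g <- fwhm / 2
  amplitude * g^2 / ((x - center)^2 + g^2)
}

# Noise-free class signal: sum of Lorentzians with class effects applied.
class_signal <- function(config, class) {
  sig <- numeric(length(config$grid))
  for (pk in config$peaks) {
    sig <- sig + lorentzian(config$grid, pk$center, pk$fwhm,
                            pk$base_amplitude * pk$class_effect[[class]])
  }
  sig
}

#' Generate a synthetic SERS mapping dataset
#'
#' For each subject of class `c`, a multiplicative gain `g_s` is drawn
#' log-normally (log-scale SD `subject_sd`); each of its spectra is
#' `g_s * sum_k Lorentzian(nu; center_k, fwhm_k, amplitude_k * effect_k(c))
#' + baseline(nu) + noise + spikes`, where the baseline is a broad smooth
#' autofluorescence curve (three Gaussians, FWHM >= 300 cm^-1, subject-
#' jittered in height and position), noise is iid normal, and spikes are
#' Poisson-distributed single-bin positive excursions of 10-50 times
#' `noise_sd`. The intervals where a class effect differs from 1 — the
#' ground truth that discriminative-band recovery is judged against — are
#' attached and retrievable with [ground_truth_bands()].
#'
#' @param config A [sim_config()].
#' @return A [spectral_dataset()] with a ground-truth band attribute.
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (any(config$n_subjects_per_class < 2)) {
    abort("need at least 2 subjects per class (cross-validation is impossible otherwise)")
  }
  grid <- config$grid
  p <- length(grid)
  span <- max(grid) - min(grid)
  # Broad autofluorescence components: positions/widths fixed, heights and
  # centers jittered per subject. All FWHM >= 300 cm^-1.
  bl_centers <- min(grid) + span * c(0.2, 0.55, 0.9)
  bl_fwhm <- c(500, 700, 400)
  bl_weight <- c(0.6, 1.0, 0.5)

  withr::with_seed(config$seed, {
    rows <- list()
    meta <- list()
    for (class in intersect(CLASS_LEVELS, names(config$n_subjects_per_class))) {
      n_sub <- config$n_subjects_per_class[[class]]
      signal_c <- class_signal(config, class)
      for (s in seq_len(n_sub)) {
        subject_id <- sprintf("%s_s%02d", class, s)
        gain <- rlnorm(1, 0, config$subject_sd)
        amp_jit <- exp(rnorm(3, 0, 0.1))
        ctr_jit <- rnorm(3, 0, 20)
        baseline <- numeric(p)
        for (j in 1:3) {
          baseline <- baseline +
            exp(-4 * log(2) * (grid - bl_centers[j] - ctr_jit[j])^2 / bl_fwhm[j]^2) *
            config$baseline_amplitude * bl_weight[j] * amp_jit[j]
        }
        n_spec <- config$spectra_per_subject
        block <- matrix(rnorm(n_spec * p, 0, config$noise_sd),
                        nrow = n_spec, ncol = p)
        block <- sweep(block, 2, gain * signal_c + baseline, `+`)
        n_spikes <- rpois(n_spec, config$spike_rate)
        for (i in which(n_spikes > 0)) {
          bins <- sample.int(p, n_spikes[i], replace = TRUE)
          block[i, bins] <- block[i, bins] +
            runif(n_spikes[i], 10, 50) * max(config$noise_sd, 1)
        }
        rows[[length(rows) + 1]] <- block
        meta[[length(meta) + 1]] <- tibble::tibble(
          spectrum_id = sprintf("%s_m%04d", subject_id, seq_len(n_spec)),
          subject_id = subject_id,
          class_label = class,
          location_index = rep_len(seq_len(config$n_locations), n_spec)
        )
      }
    }
    ds <- spectral_dataset(grid, do.call(rbind, rows), dplyr::bind_rows(meta))
  })
  attr(ds, "truth") <- simulated_effect_bands(config)
  ds
}

#' Ground-truth effect bands of a simulated dataset
#'
#' @param x A dataset from [generate_dataset()] or a [sim_config()].
#' @return Tibble with `start_cm1`, `end_cm1` (peak center +/- FWHM/2),
#'   `center`, and the per-class effect columns, one row per band whose
#'   class effect differs from 1.
#' @export
ground_truth_bands <- function(x) {
  if (inherits(x, "sim_config")) return(simulated_effect_bands(x))
  truth <- attr(x, "truth")
  if (is.null(truth)) abort("no ground-truth record attached to this dataset")
  truth
}

simulated_effect_bands <- function(config) {
  purrr::map_dfr(config$peaks, function(pk) {
    if (all(pk$class_effect == 1)) return(NULL)
    tibble::tibble(
      start_cm1 = pk$center - pk$fwhm / 2,
      end_cm1 = pk$center + pk$fwhm / 2,
      center = pk$center,
      !!!as.list(pk$class_effect)
    )
  })
}

#' The study subject roster
#'
#' The enrolment table of the pleural-effusion study this pipeline targets:
#' 34 subjects — 15 lung cancer, 7 other cancers (breast, ovarian,
#' peritoneal, two malignant mesothelioma, multiple myeloma, lymphoma) and
#' 12 non-cancer controls (8 exudate, 4 transudate). Ships as a plain-text
#' fixture so case-study grouping can be exercised without spectra.
#'
#' @return Tibble with `subject_id`, `class_label`, `diagnosis`.
#' @export
#' @examples
#' nrow(subject_roster()) # 34
subject_roster <- function() {
  path <- system.file("extdata", "pleural_subject_roster.csv",
                      package = "serschemo", mustWork = TRUE)
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(.default = readr::col_character()))
}

#' Write a simulated dataset to an output directory
#'
#' Writes the wide spectral table, the manifest, and the ground-truth effect
#' band table as delimited text.
#'
#' @param dataset A dataset from [generate_dataset()].
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(dataset, dir) {
  stopifnot(inherits(dataset, "spectral_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_wide_table(dataset, file.path(dir, "spectra_wide.csv"))
  manifest <- dplyr::mutate(dataset$meta, source_path = "simulated")
  write_manifest(manifest, file.path(dir, "manifest.csv"))
  truth <- attr(dataset, "truth")
  if (!is.null(truth)) {
    readr::write_csv(truth, file.path(dir, "ground_truth_bands.csv"))
  }
  invisible(dir)
}
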