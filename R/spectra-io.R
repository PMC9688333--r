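#' The canonical analysis wavenumber grid
#'
#' Raman shifts from 700 to 1800 cm^-1 at 1 cm^-1 spacing (1101 points), the
#' acquisition range of confocal SERS mapping of pleural fluid. A fixed common
#' grid keeps intensity matrices aligned across subjects and acquisitions;
#' spectra on instrument-native grids are placed onto it with
#' [resample_to_grid()].
#'
#' @param from,to,by Grid limits and spacing in cm^-1.
#' @return Numeric vector of wavenumbers, strictly ascending.
#' @export
#' @examples
#' length(canonical_grid()) # 1101
canonical_grid <- function(from = 700, to = 1800, by = 1) {
  seq(from, to, by = by)
}

#' Construct a single SERS spectrum
#'
#' One mapping acquisition: a wavenumber axis (Raman shift, cm^-1) with its
#' intensity vector and provenance metadata.
#'
#' @param wavenumber Strictly ascending, finite numeric vector (cm^-1).
#' @param intensity Finite numeric vector, same length (counts).
#' @param spectrum_id,subject_id Identifier strings.
#' @param location_index Positive integer: which mapping location on the
#'   substrate the spectrum came from.
#' @return An object of class `sers_spectrum`.
#' @export
sers_spectrum <- function(wavenumber, intensity, spectrum_id,
                          subject_id = NA_character_, location_index = 1L) {
  assert_finite_numeric(wavenumber, "wavenumber")
  assert_finite_numeric(intensity, "intensity")
  if (length(wavenumber) != length(intensity)) {
    abort("wavenumber and intensity must have the same length")
  }
  if (length(wavenumber) < 16) {
    abort("a spectrum needs at least 16 points")
  }
  if (any(diff(wavenumber) <= 0)) {
    if (anyDuplicated(wavenumber)) {
      abort("duplicate wavenumber values in spectrum")
    }
    abort("wavenumber must be strictly increasing")
  }
  structure(
    list(
      wavenumber = as.double(wavenumber),
      intensity = as.double(intensity),
      spectrum_id = as.character(spectrum_id),
      subject_id = as.character(subject_id),
      location_index = as.integer(location_index)
    ),
    class = "sers_spectrum"
  )
}

#' @export
print.sers_spectrum <- function(x, ...) {
  cat(sprintf(
    "<sers_spectrum> %s (subject %s, location %d): %d points, %.0f-%.0f cm^-1\n",
    x$spectrum_id, x$subject_id, x$location_index,
    length(x$wavenumber), min(x$wavenumber), max(x$wavenumber)
  ))
  invisible(x)
}

#' @export
as_tibble.sers_spectrum <- function(x, ...) {
  tibble::tibble(
    spectrum_id = x$spectrum_id,
    wavenumber = x$wavenumber,
    intensity = x$intensity
  )
}

#' Read a per-spectrum instrument text export
#'
#' Parses the two-column dialect exported by confocal Raman mapping software:
#' whitespace- or comma-separated numeric pairs (wavenumber cm^-1, intensity
#' counts), with `#`-prefixed comment lines. Files written with a descending
#' wavenumber axis are reversed (axis and intensities together) so the result
#' is always ascending.
#'
#' @param path Path to the text file.
#' @inheritParams sers_spectrum
#' @return A [sers_spectrum()].
#' @export
read_spectrum_text <- function(path, spectrum_id = NULL,
                               subject_id = NA_character_,
                               location_index = 1L) {
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  data_lines <- lines[keep]
  line_no <- which(keep)
  if (length(data_lines) < 16) {
    abort(sprintf("'%s': expected at least 16 data lines, found %d",
                  path, length(data_lines)))
  }
  fields <- strsplit(trimws(data_lines), "[,[:space:]]+")
  bad_n <- which(lengths(fields) != 2)
  if (length(bad_n) > 0) {
    abort(sprintf("'%s': line %d does not have two fields",
                  path, line_no[bad_n[1]]))
  }
  m <- matrix(suppressWarnings(as.numeric(unlist(fields))),
              ncol = 2, byrow = TRUE)
  bad <- which(rowSums(is.na(m)) > 0)
  if (length(bad) > 0) {
    abort(sprintf("'%s': non-numeric field at line %d", path, line_no[bad[1]]))
  }
  if (anyDuplicated(m[, 1])) {
    abort(sprintf("'%s': duplicate wavenumber values", path))
  }
  if (all(diff(m[, 1]) < 0)) m <- m[nrow(m):1, , drop = FALSE]
  sers_spectrum(m[, 1], m[, 2],
                spectrum_id = spectrum_id %||%
                  sub("\\.[^.]*$", "", basename(path)),
                subject_id = subject_id, location_index = location_index)
}

#' Construct an aligned spectral dataset
#'
#' The workhorse container: all spectra interpolated onto one shared
#' wavenumber grid, stored as an intensity matrix (one row per spectrum)
#' alongside a metadata tibble. The matrix is what PLS-DA consumes as its
#' descriptor matrix.
#'
#' @param grid Shared wavenumber vector (cm^-1), strictly ascending.
#' @param intensities Numeric matrix, `n_spectra x length(grid)`, no missing
#'   values.
#' @param meta Data frame with one row per spectrum and columns
#'   `spectrum_id`, `subject_id`, `class_label` (one of `"lung_cancer"`,
#'   `"other_cancer"`, `"control"`, or `NA` when unlabelled) and
#'   `location_index`.
#' @return An object of class `spectral_dataset`.
#' @export
spectral_dataset <- function(grid, intensities, meta) {
  assert_finite_numeric(grid, "grid")
  if (any(diff(grid) <= 0)) abort("grid must be strictly increasing")
  intensities <- as.matrix(intensities)
  if (ncol(intensities) != length(grid)) {
    abort("intensities must have one column per grid point")
  }
  if (anyNA(intensities) || any(!is.finite(intensities))) {
    abort("intensities must be finite with no missing values")
  }
  meta <- tibble::as_tibble(meta)
  need <- c("spectrum_id", "subject_id", "class_label", "location_index")
  missing_cols <- setdiff(need, names(meta))
  if (length(missing_cols) > 0) {
    abort(paste0("meta is missing columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (nrow(meta) != nrow(intensities)) {
    abort("meta must have one row per spectrum")
  }
  bad_class <- setdiff(unique(meta$class_label[!is.na(meta$class_label)]),
                       CLASS_LEVELS)
  if (length(bad_class) > 0) {
    abort(paste0("unknown class_label: ", paste(bad_class, collapse = ", ")))
  }
  multi <- meta |>
    dplyr::distinct(.data$subject_id, .data$class_label) |>
    dplyr::count(.data$subject_id) |>
    dplyr::filter(.data$n > 1)
  if (nrow(multi) > 0) {
    abort(paste0("subjects mapped to more than one class label: ",
                 paste(multi$subject_id, collapse = ", ")))
  }
  dimnames(intensities) <- NULL
  structure(
    list(grid = as.double(grid), intensities = intensities, meta = meta),
    class = "spectral_dataset"
  )
}

#' @export
print.spectral_dataset <- function(x, ...) {
  cls <- table(x$meta$class_label, useNA = "ifany")
  cat(sprintf(
    "<spectral_dataset> %d spectra x %d wavenumbers (%.0f-%.0f cm^-1), %d subjects\n",
    nrow(x$intensities), length(x$grid), min(x$grid), max(x$grid),
    dplyr::n_distinct(x$meta$subject_id)
  ))
  cat("  classes:", paste(names(cls), cls, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.spectral_dataset <- function(x) dim(x$intensities)

#' Long-format view of a spectral dataset
#'
#' @param x A [spectral_dataset()].
#' @param ... Unused.
#' @return A tibble with one row per (spectrum, wavenumber).
#' @export
as_tibble.spectral_dataset <- function(x, ...) {
  n <- nrow(x$intensities)
  p <- length(x$grid)
  tibble::tibble(
    spectrum_id = rep(x$meta$spectrum_id, each = p),
    subject_id = rep(x$meta$subject_id, each = p),
    class_label = rep(x$meta$class_label, each = p),
    location_index = rep(x$meta$location_index, each = p),
    wavenumber = rep(x$grid, times = n),
    intensity = as.vector(t(x$intensities))
  )
}

#' @rdname as_tibble.spectral_dataset
#' @importFrom tibble as_tibble
#' @export
tibble::as_tibble

#' Read and write dataset manifests
#'
#' A manifest is the sample sheet of a study: one row per spectrum with its
#' subject, class label, mapping location and source path. Stored as plain
#' CSV with header `spectrum_id,subject_id,class_label,location_index,source_path`.
#'
#' @param path File path.
#' @return `read_manifest()` returns the manifest tibble.
#' @export
read_manifest <- function(path) {
  m <- readr::read_csv(path, show_col_types = FALSE,
                       col_types = readr::cols(
                         spectrum_id = readr::col_character(),
                         subject_id = readr::col_character(),
                         class_label = readr::col_character(),
                         location_index = readr::col_integer(),
                         source_path = readr::col_character()
                       ))
  validate_manifest(m)
}

#' @rdname read_manifest
#' @param manifest Manifest data frame.
#' @export
write_manifest <- function(manifest, path) {
  validate_manifest(manifest)
  readr::write_csv(manifest, path)
  invisible(path)
}

validate_manifest <- function(manifest) {
  manifest <- tibble::as_tibble(manifest)
  need <- c("spectrum_id", "subject_id", "class_label", "location_index")
  missing_cols <- setdiff(need, names(manifest))
  if (length(missing_cols) > 0) {
    abort(paste0("manifest is missing columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (anyDuplicated(manifest$spectrum_id)) {
    abort("manifest spectrum_id values must be unique")
  }
  bad <- setdiff(unique(manifest$class_label), CLASS_LEVELS)
  if (length(bad) > 0) {
    abort(paste0("manifest class_label outside the closed vocabulary: ",
                 paste(bad, collapse = ", ")))
  }
  manifest
}

#' Read and write wide spectral tables
#'
#' The wide interchange format: first column `wavenumber`, one named column
#' per spectrum. `read_wide_table()` returns the dataset with spectra ordered
#' as in the manifest; ids in the manifest but absent from the table are an
#' error. The text round trip preserves intensities bit for bit.
#'
#' @param path Delimited text file path.
#' @param manifest Manifest tibble (see [read_manifest()]).
#' @return A [spectral_dataset()].
#' @export
read_wide_table <- function(path, manifest) {
  manifest <- validate_manifest(manifest)
  # base-R parsing: correctly rounded strtod, so the %.17g text written by
  # write_wide_table() round-trips doubles bit for bit
  tab <- tibble::as_tibble(utils::read.csv(path, check.names = FALSE,
                                           colClasses = "numeric"))
  if (names(tab)[1] != "wavenumber") {
    abort("first column of a wide table must be 'wavenumber'")
  }
  ids <- names(tab)[-1]
  missing_ids <- setdiff(manifest$spectrum_id, ids)
  if (length(missing_ids) > 0) {
    abort(paste0("spectra in manifest but not in table: ",
                 paste(missing_ids, collapse = ", ")))
  }
  x <- t(as.matrix(tab[manifest$spectrum_id]))
  spectral_dataset(
    grid = tab$wavenumber,
    intensities = x,
    meta = manifest[c("spectrum_id", "subject_id", "class_label",
                      "location_index")]
  )
}

#' @rdname read_wide_table
#' @param dataset A [spectral_dataset()].
#' @export
write_wide_table <- function(dataset, path) {
  stopifnot(inherits(dataset, "spectral_dataset"))
  m <- cbind(dataset$grid, t(dataset$intensities))
  # 17 significant digits: shortest text guaranteed to round-trip a double
  body <- apply(m, 1, function(row) paste(sprintf("%.17g", row), collapse = ","))
  header <- paste(c("wavenumber", dataset$meta$spectrum_id), collapse = ",")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Resample spectra onto a common wavenumber grid
#'
#' Linear interpolation of each spectrum onto `grid`; exact for locally
#' affine intensity profiles. Extrapolation is refused: every spectrum must
#' cover the full grid range.
#'
#' @param spectra A list of [sers_spectrum()] objects.
#' @param grid Target wavenumber vector (default [canonical_grid()]).
#' @param manifest Optional manifest supplying `class_label` per spectrum;
#'   when omitted, class labels are `NA`.
#' @return A [spectral_dataset()].
#' @export
resample_to_grid <- function(spectra, grid = canonical_grid(),
                             manifest = NULL) {
  stopifnot(length(spectra) > 0)
  rows <- lapply(spectra, function(s) {
    stopifnot(inherits(s, "sers_spectrum"))
    if (min(s$wavenumber) > min(grid) || max(s$wavenumber) < max(grid)) {
      abort(sprintf(
        "spectrum '%s' (%.1f-%.1f cm^-1) does not cover the grid range %.1f-%.1f",
        s$spectrum_id, min(s$wavenumber), max(s$wavenumber),
        min(grid), max(grid)
      ))
    }
    approx(s$wavenumber, s$intensity, xout = grid, method = "linear")$y
  })
  meta <- tibble::tibble(
    spectrum_id = vapply(spectra, `[[`, "", "spectrum_id"),
    subject_id = vapply(spectra, `[[`, "", "subject_id"),
    class_label = NA_character_,
    location_index = vapply(spectra, `[[`, 1L, "location_index")
  )
  if (!is.null(manifest)) {
    manifest <- validate_manifest(manifest)
    meta$class_label <- manifest$class_label[
      match(meta$spectrum_id, manifest$spectrum_id)]
  }
  spectral_dataset(grid, do.call(rbind, rows), meta)
}

#' Subset a spectral dataset by spectrum
#'
#' @param dataset A [spectral_dataset()].
#' @param idx Row indices or a logical vector over spectra.
#' @return The subsetted [spectral_dataset()].
#' @export
filter_spectra <- function(dataset, idx) {
  stopifnot(inherits(dataset, "spectral_dataset"))
  spectral_dataset(dataset$grid,
                   dataset$intensities[idx, , drop = FALSE],
                   dataset$meta[idx, ])
}
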