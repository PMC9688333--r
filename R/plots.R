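# ggplot2 displays for each result type.

#' @export
autoplot.spectral_dataset <- function(object, by_class = TRUE, ...) {
  df <- as_tibble(object)
  if (by_class) {
    df <- df |>
      dplyr::group_by(.data$class_label, .data$wavenumber) |>
      dplyr::summarise(intensity = mean(.data$intensity), .groups = "drop")
    ggplot2::ggplot(df, ggplot2::aes(.data$wavenumber, .data$intensity,
                                     colour = .data$class_label)) +
      ggplot2::geom_line() +
      ggplot2::labs(x = expression(paste("Raman shift (", cm^-1, ")")),
                    y = "Mean intensity", colour = "Class") +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(df, ggplot2::aes(.data$wavenumber, .data$intensity,
                                     group = .data$spectrum_id)) +
      ggplot2::geom_line(alpha = 0.2) +
      ggplot2::labs(x = expression(paste("Raman shift (", cm^-1, ")")),
                    y = "Intensity") +
      ggplot2::theme_minimal()
  }
}

#' @export
autoplot.vip_result <- function(object, ...) {
  p <- ggplot2::ggplot(object$scores,
                       ggplot2::aes(.data$wavenumber, .data$vip)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = object$threshold, linetype = "dashed") +
    ggplot2::labs(x = expression(paste("Raman shift (", cm^-1, ")")),
                  y = "VIP score") +
    ggplot2::theme_minimal()
  if (nrow(object$bands) > 0) {
    p <- p + ggplot2::geom_rect(
      data = object$bands, inherit.aes = FALSE,
      ggplot2::aes(xmin = .data$start_cm1, xmax = .data$end_cm1,
                   ymin = -Inf, ymax = Inf),
      alpha = 0.15, fill = "firebrick")
  }
  p
}

#' @export
autoplot.cv_report <- function(object, ...) {
  folds <- purrr::imap_dfr(object$rocs, ~dplyr::mutate(.x, fold = factor(.y)))
  ggplot2::ggplot() +
    ggplot2::geom_line(data = folds,
                       ggplot2::aes(.data$fpr, .data$tpr, group = .data$fold),
                       alpha = 0.3) +
    ggplot2::geom_line(data = object$mean_roc,
                       ggplot2::aes(.data$fpr, .data$tpr),
                       linewidth = 1, colour = "firebrick") +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    ggplot2::labs(
      x = "False positive rate", y = "True positive rate",
      title = sprintf("Fold-averaged ROC (mean AUC %.3f)",
                      object$summary$mean_auc)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.plsda <- function(object, ...) {
  if (object$ncomp < 2) abort("score scatterplot needs at least 2 latent variables")
  df <- tibble::tibble(lv1 = object$T[, 1], lv2 = object$T[, 2],
                       class = factor(object$y, levels = c(0, 1),
                                      labels = c("control", "case")))
  ggplot2::ggplot(df, ggplot2::aes(.data$lv1, .data$lv2,
                                   colour = .data$class)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::labs(x = "LV1 score", y = "LV2 score", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot class mean spectra and their difference
#'
#' @param mean_diff Output of [group_mean_difference()].
#' @return A ggplot object.
#' @export
plot_mean_difference <- function(mean_diff) {
  df <- tidyr::pivot_longer(mean_diff, c("mean_a", "mean_b", "difference"),
                            names_to = "series", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(.data$wavenumber, .data$value,
                                   colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = expression(paste("Raman shift (", cm^-1, ")")),
                  y = "Mean-centered intensity", colour = NULL) +
    ggplot2::theme_minimal()
}
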