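sh_class_colors <- c(
  background = "white", benign = "#4daf4a", cancer = "#e41a1c",
  PanIN = "#ffcc00", inflammation = "#f781bf", fiber = "#999999",
  blood = "#ff7f00", necrosis = "#984ea3", pathology = "#e41a1c"
)

#' Plot a tissue-level ROC curve
#'
#' @param object An `sh_roc`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.sh_roc <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(.data$fpr, .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         color = "grey60") +
    ggplot2::geom_step(linewidth = 0.8, color = "#e41a1c") +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "False positive rate", y = "True positive rate",
      title = sprintf("Tissue-level screening ROC (AUC %.2f, SE %.2f)",
                      object$auc, object$se)) +
    ggplot2::theme_minimal()
}

#' Plot a confusion matrix as a rate heatmap
#'
#' @param object An `sh_confusion`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.sh_confusion <- function(object, ...) {
  tb <- tidy(object)
  tb$truth <- factor(tb$truth, levels = rev(object$classes))
  tb$predicted <- factor(tb$predicted, levels = object$classes)
  ggplot2::ggplot(tb, ggplot2::aes(.data$predicted, .data$truth,
                                   fill = .data$rate)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(
      label = sprintf("%.2f", .data$rate)), size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "#377eb8",
                                 limits = c(0, 1)) +
    ggplot2::labs(x = "Predicted", y = "Truth",
                  title = sprintf("Pixel confusion (accuracy %.2f)",
                                  object$accuracy)) +
    ggplot2::theme_minimal()
}

#' Plot the metric-count accuracy sweep
#'
#' @param object An `sh_sweep`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.sh_sweep <- function(object, ...) {
  chosen <- attr(object, "chosen_k")
  ggplot2::ggplot(object, ggplot2::aes(.data$k, .data$accuracy)) +
    ggplot2::geom_line(color = "grey50") +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = chosen, linetype = 2, color = "#e41a1c") +
    ggplot2::labs(x = "Number of metrics", y = "LOMO pixel accuracy",
                  title = sprintf("Metric-count sweep (chosen k = %d)", chosen)) +
    ggplot2::theme_minimal()
}

#' Plot a class-label mask
#'
#' @param mask Integer label matrix (detailed codes, see [class_codes()]),
#'   or rapid codes with `rapid = TRUE`.
#' @param rapid Interpret codes as the rapid model's three classes.
#' @return A ggplot raster of color-coded class assignments.
#' @export
plot_label_mask <- function(mask, rapid = FALSE) {
  codes <- if (rapid) c(background = 0L, SH_RAPID_CLASSES) else SH_CLASSES
  df <- expand.grid(row = seq_len(nrow(mask)), col = seq_len(ncol(mask)))
  df$class <- factor(names(codes)[match(as.vector(mask), codes)],
                     levels = names(codes))
  ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row, fill = .data$class)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_manual(values = sh_class_colors[names(codes)],
                               drop = FALSE) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL, fill = "Class") +
    ggplot2::theme_void()
}

#' Plot mean class spectra of a phantom
#'
#' @param phantom A `mouse_phantom`.
#' @param clean Use the noise-free cube (default FALSE).
#' @return A ggplot of per-class mean absorbance spectra.
#' @export
plot_class_spectra <- function(phantom, clean = FALSE) {
  cube <- if (clean) phantom$clean_cube else phantom$cube
  codes <- sort(setdiff(unique(as.vector(phantom$labels)), 0L))
  dfs <- lapply(codes, function(cd) {
    px <- which(phantom$labels == cd)
    tibble::tibble(
      wavenumber = cube$axis,
      absorbance = colMeans(cube_spectra(cube, px)),
      class = names(SH_CLASSES)[match(cd, SH_CLASSES)]
    )
  })
  df <- dplyr::bind_rows(dfs)
  ggplot2::ggplot(df, ggplot2::aes(.data$wavenumber, .data$absorbance,
                                   color = .data$class)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_reverse() +
    ggplot2::scale_color_manual(values = sh_class_colors) +
    ggplot2::labs(x = "Wavenumber (cm⁻¹)", y = "Absorbance",
                  color = "Class") +
    ggplot2::theme_minimal()
}
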