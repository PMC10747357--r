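# ggplot2 visualisations for the main result types.

#' @exportS3Method ggplot2::autoplot
autoplot.scalogram <- function(object, ...) {
  df <- tidyr::expand_grid(
    scale = object$scales,
    time = (seq_len(ncol(object$coeffs)) - 1) * object$dt
  )
  df$magnitude <- as.vector(t(abs(object$coeffs)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$scale,
                                   fill = .data$magnitude)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(name = "|C(a,b)|") +
    ggplot2::labs(x = "time (s)", y = "scale (samples)",
                  title = sprintf("Morlet scalogram (sigma = %g)", object$sigma)) +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.scalogram_image <- function(object, ...) {
  m <- unclass(object)
  df <- tidyr::expand_grid(row = seq_len(nrow(m)), col = seq_len(ncol(m)))
  df$value <- as.vector(t(m))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 limits = c(0, 1), name = NULL) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_void()
}

#' @exportS3Method ggplot2::autoplot
autoplot.trained_model <- function(object, ...) {
  h <- tidyr::pivot_longer(object$history,
                           cols = c("train_acc", "val_acc"),
                           names_to = "set", values_to = "accuracy")
  h$set <- ifelse(h$set == "train_acc", "training", "validation")
  ggplot2::ggplot(h, ggplot2::aes(x = .data$epoch, y = .data$accuracy,
                                  colour = .data$set)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$best_epoch, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::labs(x = "epoch", y = "accuracy", colour = NULL,
                  title = "Training curves (dashed: checkpointed epoch)") +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.eval_report <- function(object, normalize = TRUE, ...) {
  m <- object$confusion
  if (normalize) {
    rs <- rowSums(m)
    nz <- rs > 0
    m[nz, ] <- m[nz, , drop = FALSE] / rs[nz]
  }
  cls <- object$per_class$class
  df <- tidyr::expand_grid(true = cls, pred = cls)
  df$value <- as.vector(t(m))
  df$true <- factor(df$true, levels = rev(cls))
  df$pred <- factor(df$pred, levels = cls)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pred, y = .data$true,
                                   fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$value)),
                       size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue",
                                 limits = c(0, max(df$value)), name = NULL) +
    ggplot2::labs(x = "predicted", y = "true",
                  title = sprintf("Confusion matrix (n = %d)", object$n)) +
    ggplot2::theme_minimal()
}

#' Plot selection evidence tables
#'
#' Entropy per shape-factor candidate and periodicity ratio per scale-count
#' candidate, with the selected values highlighted.
#'
#' @param sel A `selection_result`.
#' @return A ggplot object (two facets).
#' @export
plot_selection <- function(sel) {
  stopifnot(inherits(sel, "selection_result"))
  e <- dplyr::mutate(sel$entropies, panel = "Shannon entropy vs sigma",
                     x = .data$sigma, y = .data$entropy,
                     chosen = .data$sigma == sel$sigma_star)
  p <- dplyr::mutate(sel$periodicities, panel = "log10 periodicity vs scale count",
                     x = .data$scale_count, y = log10(.data$delta),
                     chosen = .data$scale_count == sel$scale_count_star)
  df <- dplyr::bind_rows(
    dplyr::select(e, "panel", "x", "y", "chosen"),
    dplyr::select(p, "panel", "x", "y", "chosen")
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_line(colour = "grey60") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$chosen), size = 2) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40", `TRUE` = "red"),
                                 guide = "none") +
    ggplot2::facet_wrap(~panel, scales = "free") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}
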