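#' Plot a training history
#'
#' Train/validation loss and validation accuracy per epoch.
#'
#' @param object A trained [classifier_head()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ppe_head
#' @export
autoplot.ppe_head <- function(object, ...) {
  if (is.null(object$history)) abort("head has no training history")
  long <- object$history |>
    tidyr::pivot_longer(c("train_loss", "val_loss", "val_acc"),
      names_to = "metric", values_to = "value"
    )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$value, colour = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(~ .data$metric == "val_acc",
      scales = "free_y",
      labeller = ggplot2::as_labeller(c("FALSE" = "loss", "TRUE" = "validation accuracy"))
    ) +
    ggplot2::labs(x = "epoch", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a synthetic scene with its landmarks and regions
#'
#' @param scene A list from [render_scene()] (fields `image`, `landmarks`).
#' @param cfg A [geometry_config()]; regions are drawn when their landmarks
#'   allow.
#' @param show_regions Draw the region squares (default TRUE).
#' @return A ggplot object.
#' @export
plot_scene <- function(scene, cfg = geometry_config(), show_regions = TRUE) {
  img <- scene$image
  h <- dim(img)[1]
  w <- dim(img)[2]
  p <- ggplot2::ggplot() +
    ggplot2::annotation_raster(grDevices::as.raster(img), 0, w, -h, 0) +
    ggplot2::geom_point(
      data = dplyr::filter(scene$landmarks, .data$confidence > 0),
      ggplot2::aes(x = .data$x, y = -.data$y),
      colour = "red", size = 1
    ) +
    ggplot2::coord_fixed(xlim = c(0, w), ylim = c(-h, 0), expand = FALSE) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_void()
  if (show_regions) {
    regs <- dplyr::filter(extract_regions(scene$landmarks, cfg), .data$visible)
    if (nrow(regs) > 0) {
      p <- p + ggplot2::geom_rect(
        data = regs,
        ggplot2::aes(
          xmin = .data$center_x - .data$side / 2,
          xmax = .data$center_x + .data$side / 2,
          ymin = -(.data$center_y + .data$side / 2),
          ymax = -(.data$center_y - .data$side / 2),
          colour = .data$kind
        ),
        fill = NA, linewidth = 0.5
      )
    }
  }
  p
}

#' Plot an aggregated run
#'
#' Bar chart of overall accuracy per correctness definition, with
#' per-region accuracy alongside.
#'
#' @param run A list from [aggregate_run()].
#' @return A ggplot object.
#' @export
plot_run_accuracy <- function(run) {
  df <- dplyr::bind_rows(
    dplyr::transmute(run$overall, label = .data$definition, accuracy = .data$accuracy, scope = "overall"),
    dplyr::transmute(run$per_region, label = .data$kind, accuracy = .data$accuracy, scope = "per region")
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$label, y = .data$accuracy, fill = .data$scope)) +
    ggplot2::geom_col() +
    ggplot2::scale_y_continuous(limits = c(0, 1), labels = function(x) sprintf("%.0f%%", 100 * x)) +
    ggplot2::labs(x = NULL, y = "accuracy", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}
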