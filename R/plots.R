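# Fill colors used for stage aesthetics in plots.
.stage_fill <- function() {
  pal <- default_stage_palette()
  setNames(grDevices::rgb(pal$r, pal$g, pal$b), as.character(pal$stage))
}

#' @describeIn stagewise_mape Bar chart of per-stage MAPE with the mean as
#'   a dashed line.
#' @param object A report object.
#' @export
autoplot.camu_mape_report <- function(object, ...) {
  ggplot2::ggplot(object$per_stage,
                  ggplot2::aes(x = .data$stage, y = .data$mape_pct,
                               fill = .data$stage)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::geom_hline(yintercept = object$mean_mape_pct,
                        linetype = "dashed") +
    ggplot2::scale_fill_manual(values = .stage_fill()) +
    ggplot2::labs(x = NULL, y = "MAPE (%)",
                  title = "Per-stage estimation error",
                  subtitle = sprintf("mean MAPE %.1f%%",
                                     object$mean_mape_pct)) +
    ggplot2::theme_minimal()
}

#' @describeIn aggregate_image Per-stage pulp mass and estimated
#'   concentration for one image report.
#' @param object A report object.
#' @export
autoplot.camu_image_report <- function(object, ...) {
  long <- tidyr::pivot_longer(
    object$per_stage,
    c("pulp_g", "estimated_mg_per_100g"),
    names_to = "quantity", values_to = "value"
  )
  labs <- c(pulp_g = "total pulp (g)",
            estimated_mg_per_100g = "estimated AA (mg/100 g)")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$stage, y = .data$value,
                                     fill = .data$stage)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::facet_wrap(~quantity, scales = "free_y",
                        labeller = ggplot2::as_labeller(labs)) +
    ggplot2::scale_fill_manual(values = .stage_fill()) +
    ggplot2::labs(x = NULL, y = NULL, title = "Image report by stage") +
    ggplot2::theme_minimal()
}

#' Plot an image with its detections
#'
#' Renders the raster with bounding boxes colored by stage — the quickest
#' way to eyeball detector output on a scene.
#'
#' @param image H x W x 3 array or image path.
#' @param detections Detection tibble (`x`, `y`, `w`, `h`, `stage`).
#' @return A ggplot object.
#' @export
plot_detections <- function(image, detections) {
  img <- read_image(image)
  h <- dim(img)[1]; w <- dim(img)[2]
  ggplot2::ggplot() +
    ggplot2::annotation_raster(img, xmin = 0, xmax = w, ymin = -h, ymax = 0) +
    ggplot2::geom_rect(
      data = detections,
      ggplot2::aes(xmin = .data$x, xmax = .data$x + .data$w,
                   ymin = -(.data$y + .data$h), ymax = -.data$y,
                   color = .data$stage),
      fill = NA, linewidth = 0.6
    ) +
    ggplot2::scale_color_manual(values = .stage_fill(), drop = FALSE) +
    ggplot2::coord_fixed(xlim = c(0, w), ylim = c(-h, 0), expand = FALSE) +
    ggplot2::labs(color = "stage") +
    ggplot2::theme_void()
}
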