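#' Plot a detection over its source image
#'
#' Renders the fundus image with the detected circle and centre overlaid.
#'
#' @param object An `od_circle` from [detect_od()].
#' @param image The [od_image] the detection came from (original scale).
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.od_circle <- function(object, image, ...) {
  stopifnot(inherits(image, "od_image"))
  px <- image$pixels
  df <- tibble(
    row = rep(seq_len(nrow(px)) - 1L, times = ncol(px)),
    col = rep(seq_len(ncol(px)) - 1L, each = nrow(px)),
    fill = grDevices::rgb(as.vector(px[, , 1]) / 255,
                          as.vector(px[, , 2]) / 255,
                          as.vector(px[, , 3]) / 255)
  )
  th <- seq(0, 2 * pi, length.out = 181)
  circ <- tibble(row = object$centre[1] + object$radius * sin(th),
                 col = object$centre[2] + object$radius * cos(th))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$fill)) +
    ggplot2::scale_fill_identity() +
    ggplot2::geom_path(data = circ, colour = "cyan", linewidth = 0.8) +
    ggplot2::annotate("point", x = object$centre[2], y = object$centre[1],
                      colour = "cyan", shape = 3, size = 3) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = sprintf("%s  (channel %s, r = %.0f px)",
                                  object$image_id, object$channel,
                                  object$radius),
                  x = NULL, y = NULL) +
    ggplot2::theme_void()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot per-image evaluation results
#'
#' Dot plot of the normalised centre error per image, coloured by the
#' channel the detector used, with the misdetection boundary at
#' `delta_C = 1`.
#'
#' @param object An `od_evaluation` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.od_evaluation <- function(object, ...) {
  df <- as_tibble(object)
  df$image_id <- factor(df$image_id, levels = df$image_id)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$image_id, y = .data$delta_C,
                                   colour = .data$channel)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::labs(x = NULL, y = expression(Delta * C),
                  title = "Normalised centre error per image") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5, size = 6))
}
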