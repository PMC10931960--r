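#' Render an annotation overlay
#'
#' Plots every annotated point of one image in image coordinates (y axis
#' reversed so the origin is top-left), coloured by annotator. Marker shape
#' follows the review convention: round markers are points the annotator
#' clicked directly; triangles are positions derived by calculation from
#' annotated bone contours (the contour-based femoral-head centre and the
#' sacral-endplate midpoint), which are added to the plot when the
#' underlying contours are present. An optional background raster (numeric
#' matrix or array, e.g. a decoded radiograph) is drawn underneath.
#'
#' @param landmarks A validated landmark table.
#' @param image_id Image to render.
#' @param background Optional raster matrix/array drawn under the points.
#' @param out Optional PNG path; when given the plot is also written there.
#' @param width,height PNG size in inches.
#' @return The ggplot object, invisibly when `out` is given.
#' @export
render_overlay <- function(landmarks, image_id, background = NULL,
                           out = NULL, width = 6, height = 6) {
  lm <- landmarks[landmarks$image_id == image_id, ]
  pts <- tibble::tibble(annotator_id = lm$annotator_id,
                        x = lm$x, y = lm$y, source = "clicked")
  derived <- review_positions(lm)
  derived <- derived[derived$landmark %in%
                       c("femoral_head_centre_cal", "sacral_midpoint_cal") &
                       !is.na(derived$x), ]
  if (nrow(derived) > 0) {
    pts <- dplyr::bind_rows(
      pts, tibble::tibble(annotator_id = derived$annotator_id,
                          x = derived$x, y = derived$y, source = "derived"))
  }
  p <- ggplot2::ggplot()
  if (!is.null(background)) {
    g <- grDevices::as.raster(background / max(background, 1))
    p <- p + ggplot2::annotation_raster(
      g, xmin = 0, xmax = ncol(as.matrix(background)),
      ymin = -nrow(as.matrix(background)), ymax = 0)
  }
  p <- p +
    ggplot2::geom_point(
      data = pts,
      ggplot2::aes(x = .data$x, y = -.data$y, colour = .data$annotator_id,
                   shape = .data$source),
      size = 2.5) +
    ggplot2::scale_shape_manual(
      values = c(clicked = 16, derived = 17),
      labels = c(clicked = "clicked point (round)",
                 derived = "calculated from contour (triangle)"),
      drop = FALSE) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (px)", y = "-y (px, image rows)",
                  colour = "annotator", shape = "annotation source",
                  title = paste("Annotations for image", image_id)) +
    ggplot2::theme_minimal()
  if (!is.null(out)) {
    ggplot2::ggsave(out, p, width = width, height = height, dpi = 150)
    return(invisible(p))
  }
  p
}
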