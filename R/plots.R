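# ggplot2 display functions for the main result types.

#' Plot per-loop F1 curves
#'
#' One line per fold (or per condition when a `condition` column is
#' present, as in the benchmark output), with the loop index on the x axis.
#' @param curves An `f1_curve` tibble or the `curves` element of
#'   [run_outcome_benchmark()].
#' @return A ggplot object.
#' @export
plot_f1_curves <- function(curves) {
  has_cond <- "condition" %in% names(curves)
  p <- ggplot2::ggplot(curves,
         ggplot2::aes(x = .data$loop, y = .data$f1,
                      group = interaction(.data$fold_id,
                        if (has_cond) .data$condition else "")))
  if (has_cond) {
    p <- p + ggplot2::geom_line(ggplot2::aes(colour = .data$condition),
                                alpha = 0.8)
  } else {
    p <- p + ggplot2::geom_line(alpha = 0.8)
  }
  p + ggplot2::labs(x = "loop (time point)", y = "weighted F1") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.f1_curve <- function(object, ...) plot_f1_curves(object)

#' Plot heterogeneity over time
#'
#' Mean pairwise inter-organoid PC-space distance per loop.
#' @param per_loop Output of [inter_organoid_distance()] (or the
#'   `per_loop` element of [heterogeneity_trend()]).
#' @return A ggplot object.
#' @export
plot_heterogeneity <- function(per_loop) {
  ggplot2::ggplot(per_loop,
      ggplot2::aes(x = .data$loop, y = .data$mean_distance)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "loop (time point)",
                  y = "mean pairwise PC-space distance") +
    ggplot2::theme_minimal()
}

#' Display a frame with its mask outline
#'
#' Quick-look raster of a grayscale frame, optionally overlaying the mask
#' boundary.
#' @param image Grayscale matrix.
#' @param mask Optional binary mask.
#' @return A ggplot object.
#' @export
plot_frame <- function(image, mask = NULL) {
  d <- tidyr::expand_grid(row = seq_len(nrow(image)),
                          col = seq_len(ncol(image)))
  d$value <- image[cbind(d$row, d$col)]
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$col, y = .data$row,
                                       fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 guide = "none") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::theme_void()
  if (!is.null(mask)) {
    b <- which((mask - (mask & EBImage::erode(EBImage::Image(mask * 1)) > 0)) > 0,
               arr.ind = TRUE)
    if (nrow(b)) {
      bd <- tibble::tibble(row = b[, 1], col = b[, 2])
      p <- p + ggplot2::geom_point(data = bd,
             ggplot2::aes(x = .data$col, y = .data$row),
             inherit.aes = FALSE, colour = "green", size = 0.1)
    }
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
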