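#' Plot an image array, a phantom, or a label mask
#'
#' `plot_image()` renders any 0..255 RGB array with ggplot2;
#' `autoplot.pq_phantom()` shows a phantom's rendered tile; `plot_mask()`
#' renders a tissue label mask in the conventional display colors (blue
#' background, black normal tissue, white abnormal tissue).
#'
#' @param image rows x cols x 3 array, 0..255.
#' @return A ggplot object.
#' @export
plot_image <- function(image) {
  h <- dim(image)[1]; w <- dim(image)[2]
  df <- expand.grid(row = seq_len(h), col = seq_len(w))
  df$fill <- grDevices::rgb(image[, , 1] / 255, image[, , 2] / 255,
                            image[, , 3] / 255)
  ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$fill)) +
    ggplot2::scale_fill_identity() +
    ggplot2::scale_y_reverse(expand = c(0, 0)) +
    ggplot2::scale_x_continuous(expand = c(0, 0)) +
    ggplot2::coord_fixed() +
    ggplot2::theme_void()
}

#' @rdname plot_image
#' @param object A `pq_phantom`.
#' @param ... Unused.
#' @method autoplot pq_phantom
#' @export
autoplot.pq_phantom <- function(object, ...) {
  plot_image(object$image)
}

#' @rdname plot_image
#' @param mask Integer matrix of codes 0/1/2.
#' @export
plot_mask <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  df <- expand.grid(row = seq_len(h), col = seq_len(w))
  df$class <- factor(c("background", "normal", "abnormal")[mask + 1L],
                     levels = c("background", "normal", "abnormal"))
  ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$class)) +
    ggplot2::scale_fill_manual(values = c(background = "#3366CC",
                                          normal = "#000000",
                                          abnormal = "#FFFFFF")) +
    ggplot2::scale_y_reverse(expand = c(0, 0)) +
    ggplot2::scale_x_continuous(expand = c(0, 0)) +
    ggplot2::coord_fixed() +
    ggplot2::theme_void()
}

#' Nucleus classification overlay
#'
#' Shows the rendered image with detected nuclei outlined at their
#' centroids, red for normal (spindle) and green for abnormal (round).
#'
#' @param image rows x cols x 3 array, 0..255.
#' @param nuclei Classified nucleus tibble from [classify_nuclei()].
#' @return A ggplot object.
#' @export
plot_nuclei_overlay <- function(image, nuclei) {
  plot_image(image) +
    ggplot2::geom_point(
      data = nuclei,
      ggplot2::aes(.data$centroid_col, .data$centroid_row,
                   color = .data$class),
      shape = 1, size = 3, stroke = 1
    ) +
    ggplot2::scale_color_manual(values = c(normal = "red",
                                           abnormal = "green"))
}

#' Severity boxplots by grade
#'
#' The study's descriptive figure: box-and-whisker plots of specimen-level
#' Abn-SR and Abn-NR by pathological grade and by clinical severity
#' classification.
#'
#' @param object A `pq_study` from [run_study()].
#' @param ... Unused.
#' @return A ggplot object (faceted by parameter and grading system).
#' @method autoplot pq_study
#' @export
autoplot.pq_study <- function(object, ...) {
  df <- object$per_specimen |>
    tidyr::pivot_longer(c("mean_abn_sr", "mean_abn_nr"),
                        names_to = "parameter", values_to = "value") |>
    tidyr::pivot_longer(c("pathological_grade", "clinical_grade"),
                        names_to = "grouping", values_to = "grade") |>
    dplyr::mutate(
      parameter = dplyr::recode(.data$parameter,
                                mean_abn_sr = "Abn-SR",
                                mean_abn_nr = "Abn-NR"),
      grade = factor(.data$grade,
                     levels = c("L", "M", "H", "I", "II", "III", "IV"))
    )
  ggplot2::ggplot(df, ggplot2::aes(.data$grade, .data$value)) +
    ggplot2::geom_boxplot(outlier.shape = 1) +
    ggplot2::facet_grid(parameter ~ grouping, scales = "free") +
    ggplot2::labs(x = NULL, y = "ratio") +
    ggplot2::theme_bw()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
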