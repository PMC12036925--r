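#' Plot one slice of a quantitative map
#'
#' @param object A [quantitative_map()].
#' @param slice Slice index (default: central slice).
#' @param ... Unused.
#' @return A ggplot raster of the slice (masked voxels blank).
#' @export
autoplot.quantitative_map <- function(object, slice = NULL, ...) {
  d <- dim(object$values)
  if (is.null(slice)) slice <- ceiling(d[3] / 2)
  df <- tidy(object) |> dplyr::filter(.data$z == slice)
  df$value[!df$valid] <- NA_real_
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(na.value = "grey90",
                                  name = paste0(object$parameter,
                                                if (nzchar(object$unit))
                                                  paste0(" [", object$unit, "]")
                                                else "")) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL,
                  title = sprintf("%s, slice %d", object$parameter, slice)) +
    ggplot2::theme_minimal()
}

#' Plot a single-voxel spectrum
#'
#' Magnitude spectrum with the conventional reversed ppm axis.
#'
#' @param object An [mrs_spectrum()].
#' @param ... Unused.
#' @return A ggplot line plot.
#' @export
autoplot.mrs_spectrum <- function(object, ...) {
  df <- tibble::tibble(ppm = object$ppm, magnitude = Mod(object$signal))
  ggplot2::ggplot(df, ggplot2::aes(.data$ppm, .data$magnitude)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = "chemical shift [ppm]", y = "magnitude [a.u.]") +
    ggplot2::theme_minimal()
}

#' Bar plot of per-muscle record means
#'
#' @param records Muscle-record tibble ([aggregate_muscle()]).
#' @return A ggplot bar chart of retained records, one facet per parameter.
#' @export
plot_muscle_records <- function(records) {
  df <- dplyr::filter(records, !.data$excluded)
  ggplot2::ggplot(df, ggplot2::aes(.data$muscle, .data$mean_value,
                                   fill = .data$side)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(ggplot2::vars(.data$parameter), scales = "free_y") +
    ggplot2::labs(x = NULL, y = "muscle mean") +
    ggplot2::theme_minimal()
}
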