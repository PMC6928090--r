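#' Plot a height map as a raster
#'
#' @param object A `height_map` (single frame).
#' @param ... Unused.
#' @return A ggplot object; invalid cells are blank.
#' @method autoplot height_map
#' @export
autoplot.height_map <- function(object, ...) {
  grid <- attr(object, "grid", exact = TRUE)
  s <- grid$spacing
  ggplot2::ggplot(
    dplyr::filter(object, .data$valid),
    ggplot2::aes(x = (.data$i + 0.5) * s + grid$origin[1],
                 y = (.data$j + 0.5) * s + grid$origin[2],
                 fill = .data$h)
  ) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "height (Å)") +
    ggplot2::coord_fixed() +
    ggplot2::labs(
      x = "x (Å)", y = "y (Å)",
      title = paste0(attr(object, "leaflet", exact = TRUE),
                     " leaflet height map")
    )
}

#' Deformation time series plot
#'
#' @param ds A `deformation_series`.
#' @return A ggplot of deformation vs time.
#' @export
plot_deformation <- function(ds) {
  ggplot2::ggplot(ds, ggplot2::aes(x = .data$time,
                                   y = .data$deformation)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "time (ns)", y = "deformation (Å)",
                  title = "top-bottom surface deformation")
}

#' Hill/valley category distribution bar chart
#'
#' @param dist Output of [cumulative_category_distribution()].
#' @return A ggplot faceted by side.
#' @export
plot_category_distribution <- function(dist) {
  ggplot2::ggplot(dist, ggplot2::aes(x = .data$category,
                                     y = .data$fraction,
                                     fill = .data$category)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::facet_wrap(~side) +
    ggplot2::labs(x = "deformation category", y = "fraction",
                  title = "cumulative hill/valley category distribution")
}

#' Strain-rate time series plot
#'
#' @param ks A `kinematics_series`.
#' @return A ggplot of strain rate vs time.
#' @export
plot_strain_rate <- function(ks) {
  ggplot2::ggplot(ks, ggplot2::aes(x = .data$time,
                                   y = .data$strain_rate)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::labs(x = "time (ns)",
                  y = expression(dot(epsilon)[zx] ~ (ns^-1)),
                  title = "inter-leaflet shear strain rate")
}

#' Protein-proximity heights plot
#'
#' Local ring height, global membrane height and protein COM height over
#' time on one panel.
#'
#' @param ps A `proximity_series`.
#' @return A ggplot.
#' @export
plot_proximity <- function(ps) {
  long <- tidyr::pivot_longer(
    dplyr::select(ps, "time", "local_height", "global_height", "com_z"),
    -"time", names_to = "series", values_to = "height"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time, y = .data$height,
                                     colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (ns)", y = "height (Å)",
                  title = "membrane heights near the protein")
}
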