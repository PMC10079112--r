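#' Plot an immune response density
#'
#' @param object A [response_density()].
#' @param ... Unused.
#' @return A ggplot: peak-normalized density of inducibility, 0 = fully
#'   constitutive, 1 = fully induced.
#' @export
autoplot.response_density <- function(object, ...) {
  df <- tibble::tibble(inducibility = object$x, density = object$y)
  ggplot2::ggplot(df, ggplot2::aes(.data$inducibility, .data$density)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::labs(x = "proportion of response induced by parasites",
                  y = "relative density (peak = 1)") +
    ggplot2::theme_minimal()
}

#' Plot a joint magnitude/inducibility density
#'
#' @param object A [magnitude_inducibility_density()] result.
#' @param ... Unused.
#' @return A ggplot raster of the pooled 2D density.
#' @export
autoplot.response_density_2d <- function(object, ...) {
  df <- tidyr::expand_grid(i = seq_along(object$x),
                           j = seq_along(object$y))
  df$inducibility <- object$x[df$i]
  df$effector_peak <- object$y[df$j]
  df$density <- object$z[cbind(df$i, df$j)]
  ggplot2::ggplot(df, ggplot2::aes(.data$inducibility,
                                   .data$effector_peak,
                                   fill = .data$density)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "proportion of response induced",
                  y = "peak effector abundance", fill = "density") +
    ggplot2::theme_minimal()
}

#' Plot the trajectory of a simulation run
#'
#' @param object A `coevolution_run` or `competition_run`.
#' @param metrics Summary columns to facet (defaults to fitness,
#'   inducibility, connectivity, and network size).
#' @param ... Unused.
#' @return A ggplot of per-generation population means.
#' @export
autoplot.coevolution_run <- function(object,
                                     metrics = c("mean_fitness",
                                                 "mean_inducibility",
                                                 "mean_connectivity",
                                                 "mean_network_size"),
                                     ...) {
  df <- object$summary |>
    dplyr::select("generation", dplyr::all_of(metrics)) |>
    tidyr::pivot_longer(-"generation", names_to = "metric")
  ggplot2::ggplot(df, ggplot2::aes(.data$generation, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "generation", y = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.coevolution_run
#' @export
autoplot.competition_run <- function(object, ...) {
  df <- object$summary |>
    dplyr::filter(.data$phase == "competition") |>
    dplyr::mutate(generation = dplyr::row_number()) |>
    dplyr::select("generation", pleiotropic = "n_pleiotropic",
                  non_pleiotropic = "n_non_pleiotropic") |>
    tidyr::pivot_longer(-"generation", names_to = "type",
                        values_to = "hosts")
  ggplot2::ggplot(df, ggplot2::aes(.data$generation, .data$hosts,
                                   colour = .data$type)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::labs(x = "merged generation", y = "hosts",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
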