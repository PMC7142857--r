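# ggplot2 visualisation helpers. Every result type gets an autoplot() so the
# usual `autoplot(x)` idiom works straight from the pipe.

raster_to_tibble <- function(x) {
  cc <- cell_centres(x$grid)
  tibble::tibble(
    x = rep(cc$x, each = x$grid$n_y),
    y = rep(cc$y, times = x$grid$n_x),
    value = as.numeric(x$values)
  )
}

#' Plot a raster field
#'
#' @param object A [raster_field()].
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.raster_field <- function(object, ...) {
  df <- raster_to_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::coord_equal() +
    ggplot2::scale_fill_viridis_c(name = object$units) +
    ggplot2::labs(title = object$name, x = "x [m]", y = "y [m]") +
    ggplot2::theme_minimal()
}

#' Plot per-environment exposure maps
#'
#' Faceted maps of the per-cell exposure in every environment of an
#' `exposure_result`.
#'
#' @param object An `exposure_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.exposure_result <- function(object, ...) {
  cc <- cell_centres(object$grid)
  df <- purrr::imap(object$envs, function(m, env) {
    tibble::tibble(
      environment = env,
      x = rep(cc$x, each = object$grid$n_y),
      y = rep(cc$y, times = object$grid$n_x),
      exposure = as.numeric(m)
    )
  }) |> dplyr::bind_rows()
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y, fill = .data$exposure)) +
    ggplot2::geom_raster() +
    ggplot2::coord_equal() +
    ggplot2::facet_wrap(~environment) +
    ggplot2::scale_fill_viridis_c(name = "ug/m3 x persons") +
    ggplot2::labs(
      title = sprintf("Total %s exposure (%s approach)", object$pollutant, object$approach),
      x = "x [m]", y = "y [m]"
    ) +
    ggplot2::theme_minimal()
}

#' Plot per-environment PWE
#'
#' @param object A `pwe_result`.
#' @param ... Unused.
#' @return A ggplot bar chart of PWE per environment.
#' @exportS3Method ggplot2::autoplot
autoplot.pwe_result <- function(object, ...) {
  df <- object$by_environment |> dplyr::filter(is.finite(.data$pwe))
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$environment, .data$pwe),
                                   y = .data$pwe)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(
      title = sprintf("Population-weighted %s exposure (%s approach)",
                      object$pollutant, object$approach),
      x = NULL, y = "PWE [ug/m3]"
    ) +
    ggplot2::theme_minimal()
}

#' Plot a sensitivity report
#'
#' @param object A `sensitivity_report` from [run_sensitivity()].
#' @param ... Unused.
#' @return A ggplot of exposure changes per environment and scenario.
#' @exportS3Method ggplot2::autoplot
autoplot.sensitivity_report <- function(object, ...) {
  df <- object |> dplyr::filter(.data$scenario != "reference")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$environment,
                                   y = .data$exposure_change_pct,
                                   fill = .data$scenario)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "Total-exposure change vs reference [%]") +
    ggplot2::theme_minimal()
}
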