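#' Plot a line cut
#'
#' Intensity versus `q_par` with error bars, log-scaled intensity.
#'
#' @param object A `line_cut`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.line_cut <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$qpar, y = .data$intensity)) +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = pmax(.data$intensity - .data$sigma, 1e-12),
      ymax = .data$intensity + .data$sigma), size = 0.15) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = expression(q["||"] ~ (ring(A)^-1)),
                  y = "intensity (a.u.)",
                  title = sprintf("line cut at qz = %.4g 1/A",
                                  attr(object, "qz_center"))) +
    ggplot2::theme_minimal()
}

#' Plot a reflectivity profile
#'
#' @param object A `reflectivity_profile`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.reflectivity_profile <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$qz, y = .data$intensity)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = expression(q[z] ~ (ring(A)^-1)),
                  y = "intensity (a.u.)",
                  title = "meridional reflectivity") +
    ggplot2::theme_minimal()
}

#' Plot a structure-factor map
#'
#' Log-intensity heat map over `(q_par, q_z)`; the diffuse lobes appear
#' as bands centered at multiples of `q1`.
#'
#' @param object An `sf_map` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sf_map <- function(object, ...) {
  df <- as_tibble(object)
  df$log_intensity <- log10(pmax(df$intensity, max(df$intensity) * 1e-8))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$qpar, y = .data$qz,
                                   fill = .data$log_intensity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "log10 S") +
    ggplot2::labs(x = expression(q["||"] ~ (ring(A)^-1)),
                  y = expression(q[z] ~ (ring(A)^-1))) +
    ggplot2::theme_minimal()
}

#' Plot a fit: data and best-fit curves per cut
#'
#' @param object A `caille_fit`.
#' @param ... Unused.
#' @return A ggplot object faceted by cut position.
#' @export
autoplot.caille_fit <- function(object, ...) {
  df <- augment(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$qpar, y = .data$intensity)) +
    ggplot2::geom_point(data = df[df$kind == "data", ], size = 0.4,
                        alpha = 0.6) +
    ggplot2::geom_line(data = df[df$kind == "fit", ], color = "red") +
    ggplot2::scale_y_log10() +
    ggplot2::facet_wrap(~round(qz, 4), scales = "free_y",
                        labeller = ggplot2::label_both) +
    ggplot2::labs(x = expression(q["||"] ~ (ring(A)^-1)),
                  y = "intensity (a.u.)") +
    ggplot2::theme_minimal()
}
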