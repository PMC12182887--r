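#' Plot a normalized NND histogram
#'
#' @param object An `nnd_histogram`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.nnd_histogram <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$bin_mid, y = .data$density)) +
    ggplot2::geom_col(width = attr(object, "bin_size"), fill = "grey35") +
    ggplot2::labs(x = "NND (nm)", y = "density (1/nm)") +
    ggplot2::theme_minimal()
}

#' Plot a delta-area comparison
#'
#' Experimental and CSR densities with the positive excess (the delta
#' area) shaded.
#'
#' @param object A `delta_area` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.delta_area <- function(object, ...) {
  d <- object$differences
  long <- tidyr::pivot_longer(d, c("density_experimental", "density_csr"),
                              names_to = "curve", values_to = "density",
                              names_prefix = "density_")
  ggplot2::ggplot() +
    ggplot2::geom_ribbon(data = d,
                         ggplot2::aes(x = .data$bin_mid,
                                      ymin = .data$density_csr,
                                      ymax = .data$density_csr + .data$positive_part),
                         fill = "tomato", alpha = 0.4) +
    ggplot2::geom_step(data = long,
                       ggplot2::aes(x = .data$bin_mid, y = .data$density,
                                    color = .data$curve)) +
    ggplot2::labs(x = "NND (nm)", y = "density (1/nm)",
                  title = sprintf("delta area = %.3f", object$delta_area)) +
    ggplot2::theme_minimal()
}

#' Plot an axial profile
#'
#' @param object An `axial_profile`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.axial_profile <- function(object, ...) {
  h <- object$histogram
  fit <- tibble::tibble(
    z = seq(min(h$bin_left), max(h$bin_right), length.out = 200)
  )
  fit$count <- max(h$count) * exp(-(fit$z - object$peak)^2 / (2 * object$width^2))
  ggplot2::ggplot(h, ggplot2::aes(x = .data$bin_mid, y = .data$count)) +
    ggplot2::geom_col(width = object$bin_size, fill = "grey55") +
    ggplot2::geom_line(data = fit, ggplot2::aes(x = .data$z, y = .data$count),
                       color = "tomato") +
    ggplot2::geom_vline(xintercept = object$peak, linetype = 2) +
    ggplot2::labs(x = "z (nm)", y = "count",
                  title = sprintf("channel %s: peak %.1f nm", object$channel, object$peak)) +
    ggplot2::theme_minimal()
}

#' Plot per-condition mean NND curves with SD bands
#'
#' The condition summary figure: per analysis, the mean experimental
#' curve with its population-SD ribbon and the CSR null curve.
#'
#' @param object A `condition_result`.
#' @param ... Unused.
#' @return A ggplot faceted by analysis.
#' @export
autoplot.condition_result <- function(object, ...) {
  ggplot2::ggplot(object$curves,
                  ggplot2::aes(x = .data$bin_mid, y = .data$mean_density,
                               color = .data$curve, fill = .data$curve)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = pmax(0, .data$mean_density - .data$sd_density),
                                      ymax = .data$mean_density + .data$sd_density),
                         alpha = 0.25, color = NA) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~analysis, scales = "free_y") +
    ggplot2::labs(x = "NND (nm)", y = "density (1/nm)", title = object$condition) +
    ggplot2::theme_minimal()
}
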