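#' Plot methods
#'
#' ggplot2 graphics for the package's result types: point patterns over their
#' windows, intensity surfaces, summary-function estimates and Monte-Carlo
#' envelopes (observed curve, envelope ribbon, CSR reference).
#'
#' @param object,x An object of the relevant class.
#' @param ... Unused.
#' @return A ggplot object.
#' @name plots
NULL

#' @rdname plots
#' @export
plot_pattern <- function(x, ...) {
  w <- pattern_window(x)
  ring <- data.frame(x = c(w$x, w$x[1]), y = c(w$y, w$y[1]))
  gg <- ggplot2::ggplot() +
    ggplot2::geom_path(data = ring, ggplot2::aes(x = .data$x, y = .data$y),
                       colour = "grey40") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (m)", y = "y (m)") +
    ggplot2::theme_minimal()
  df <- as.data.frame(x)
  if (is_marked(x)) {
    gg + ggplot2::geom_point(
      data = df,
      ggplot2::aes(x = .data$x, y = .data$y, colour = .data$taxon),
      size = 1.2
    )
  } else {
    gg + ggplot2::geom_point(data = df,
                             ggplot2::aes(x = .data$x, y = .data$y),
                             size = 1.2)
  }
}

#' @rdname plots
#' @exportS3Method ggplot2::autoplot
autoplot.point_pattern <- function(object, ...) plot_pattern(object, ...)

#' @rdname plots
#' @exportS3Method ggplot2::autoplot
autoplot.intensity_surface <- function(object, ...) {
  ggplot2::ggplot(as.data.frame(object),
                  ggplot2::aes(x = .data$x, y = .data$y,
                               fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::coord_equal() +
    ggplot2::scale_fill_viridis_c(name = expression(lambda ~ (m^-2))) +
    ggplot2::labs(x = "x (m)", y = "y (m)") +
    ggplot2::theme_minimal()
}

#' @rdname plots
#' @exportS3Method ggplot2::autoplot
autoplot.fn_estimate <- function(object, ...) {
  variant <- attr(object, "variant")
  ref <- if (grepl("^pcf", variant)) 1 else NULL
  df <- as.data.frame(object)
  gg <- ggplot2::ggplot(df, ggplot2::aes(x = .data$r, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "r (m)", y = variant) +
    ggplot2::theme_minimal()
  if (!is.null(ref)) {
    gg <- gg + ggplot2::geom_hline(yintercept = ref, linetype = "dotted",
                                   colour = "red")
  } else if (variant %in% c("L", "L_cross")) {
    gg <- gg + ggplot2::geom_abline(slope = 1, intercept = 0,
                                    linetype = "dotted", colour = "red")
  }
  gg
}

#' @rdname plots
#' @exportS3Method ggplot2::autoplot
autoplot.envelope_result <- function(object, ...) {
  variant <- attr(object, "variant")
  df <- as.data.frame(object)
  gg <- ggplot2::ggplot(df, ggplot2::aes(x = .data$r)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
                         fill = "grey75", alpha = 0.7) +
    ggplot2::geom_line(ggplot2::aes(y = .data$obs)) +
    ggplot2::labs(
      x = "r (m)", y = variant,
      title = sprintf("%s with %d-simulation envelope (rank %d)",
                      variant, attr(object, "n_sim"), attr(object, "rank"))
    ) +
    ggplot2::theme_minimal()
  if (grepl("^pcf", variant)) {
    gg <- gg + ggplot2::geom_hline(yintercept = 1, linetype = "dotted",
                                   colour = "red")
  } else if (grepl("^L", variant)) {
    gg <- gg + ggplot2::geom_abline(slope = 1, intercept = 0,
                                    linetype = "dotted", colour = "red")
  }
  gg
}
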