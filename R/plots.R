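# ggplot2 visualisations for the main result types.

#' Plot a calibration curve with its confidence band
#'
#' Draws the fitted bead-density-to-stiffness curve, its two-sided band at
#' the model's confidence level (dashed), and optionally the calibration
#' points with their density/stiffness error bars.
#'
#' @param object A `gel_calibration`.
#' @param points Optional `calibration_points` to overlay.
#' @param n Number of curve evaluation points.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gel_calibration <- function(object, points = NULL, n = 200, ...) {
  dom <- object$density_domain
  if (object$kind == "logit") {
    lim <- object$coef[c("x_lo", "x_hi")]
    pad <- 1e-6 * diff(lim)
    dom <- c(max(dom[1], lim[1] + pad), min(dom[2], lim[2] - pad))
  }
  grid <- seq(dom[1], dom[2], length.out = n)
  band <- predict(object, grid)
  p <- ggplot2::ggplot(band, ggplot2::aes(x = .data$density)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$ci_low,
                                      ymax = .data$ci_high),
                         alpha = 0.15) +
    ggplot2::geom_line(ggplot2::aes(y = .data$ci_low), linetype = "dashed") +
    ggplot2::geom_line(ggplot2::aes(y = .data$ci_high), linetype = "dashed") +
    ggplot2::geom_line(ggplot2::aes(y = .data$stiffness_kpa)) +
    ggplot2::labs(x = expression("Bead density (per" ~ 10^4 ~ mu * m^2 * ")"),
                  y = "Young's modulus (kPa)",
                  title = sprintf("%s calibration", object$kind))
  if (!is.null(points)) {
    xy <- tibble(density = points[["density_mean"]] %||% points[["density"]],
                 stiffness = points[["stiffness_mean"]] %||%
                   points[["stiffness_kpa"]],
                 dsem = points[["density_sem"]] %||% 0,
                 ssem = points[["stiffness_sem"]] %||% 0)
    p <- p +
      ggplot2::geom_errorbar(
        data = xy, ggplot2::aes(x = .data$density,
                                ymin = .data$stiffness - .data$ssem,
                                ymax = .data$stiffness + .data$ssem),
        width = 0, na.rm = TRUE) +
      ggplot2::geom_errorbarh(
        data = xy, ggplot2::aes(y = .data$stiffness,
                                xmin = .data$density - .data$dsem,
                                xmax = .data$density + .data$dsem),
        height = 0, na.rm = TRUE, inherit.aes = FALSE) +
      ggplot2::geom_point(data = xy,
                          ggplot2::aes(x = .data$density,
                                       y = .data$stiffness))
  }
  p
}

plot_map <- function(map, value, label) {
  ggplot2::ggplot(map, ggplot2::aes(x = .data$x_mm, y = .data$y_mm,
                                    fill = .data[[value]])) +
    ggplot2::geom_tile() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (mm)", y = "y (mm)", fill = label)
}

#' @export
autoplot.bead_density_map <- function(object, ...) {
  plot_map(object, "density", expression("beads /" ~ 10^4 ~ mu * m^2))
}

#' @export
autoplot.stiffness_map <- function(object, ...) {
  plot_map(object, "stiffness_kpa", "E (kPa)")
}

#' @export
autoplot.force_curve <- function(object, fit = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$position_um,
                                            y = .data$force_nN)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.6) +
    ggplot2::labs(x = expression("Piezo position (" * mu * "m)"),
                  y = "Force (nN)")
  if (!is.null(fit)) {
    k <- attr(object, "spring_constant_n_m")
    delta <- indentation_um(object$position_um, object$force_nN,
                            fit$contact_um, k, fit$baseline_nN)
    pred <- fit$baseline_nN + hertz_force(delta, fit$E_kpa,
                                          attr(object, "tip_radius_um"),
                                          attr(object, "poisson_ratio"))
    p <- p + ggplot2::geom_line(
      data = tibble(position_um = object$position_um, force_nN = pred),
      colour = "red")
  }
  p
}

#' @export
autoplot.length_stiffness_fit <- function(object, records = NULL, n = 200, ...) {
  dat <- object$fit_log$model
  Erange <- range(exp(dat[["log(E)"]]))
  grid <- tibble(E = seq(Erange[1], Erange[2], length.out = n))
  grid$L <- object$alpha + object$beta * log(grid$E)
  p <- ggplot2::ggplot(grid, ggplot2::aes(x = .data$E, y = .data$L)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Young's modulus (kPa)", y = expression(
      "Adhesion length (" * mu * "m)"))
  if (!is.null(records))
    p <- p + ggplot2::geom_point(
      data = records, ggplot2::aes(x = .data$stiffness_kpa,
                                   y = .data$length_um),
      alpha = 0.5)
  p
}

#' Display a log-scaled ratio image
#'
#' Renders the [log_display()] RGB image (jet-like scale over
#' \[0.1, 10\], grey for zero pixels) as a ggplot raster.
#'
#' @param r A `ratio_image`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ratio_image <- function(r, ...) {
  rgb_arr <- log_display(r)
  nr <- dim(rgb_arr)[1]; nc <- dim(rgb_arr)[2]
  raster <- grDevices::rgb(rgb_arr[, , 1], rgb_arr[, , 2], rgb_arr[, , 3])
  dim(raster) <- c(nr, nc)
  ggplot2::ggplot() +
    ggplot2::annotation_raster(raster, xmin = 0, xmax = nc, ymin = 0,
                               ymax = nr) +
    ggplot2::xlim(0, nc) + ggplot2::ylim(0, nr) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (px)", y = "y (px)")
}
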