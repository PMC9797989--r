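# ggplot2 visualisation of the package's result types.

#' Plot a motion series
#'
#' Boundary outlines across the cycle, with the device frame when embedded.
#'
#' @param object A `motion_series`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.motion_series <- function(object, ...) {
  df <- as_tibble(object)
  pl <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                         group = .data$frame,
                                         colour = .data$time)) +
    ggplot2::geom_path() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (mm)", y = "y (mm)", colour = "time (s)") +
    ggplot2::theme_minimal()
  if (!is.null(object$device)) {
    seg <- dplyr::bind_rows(lapply(seq_along(object$device$segments), function(i) {
      sg <- object$device$segments[[i]]
      tibble(xa = sg[1, 1], ya = sg[1, 2], xb = sg[2, 1], yb = sg[2, 2])
    }))
    pl <- pl + ggplot2::geom_segment(
      data = seg, ggplot2::aes(x = .data$xa, y = .data$ya,
                               xend = .data$xb, yend = .data$yb),
      inherit.aes = FALSE, linewidth = 1.2)
  }
  pl
}

#' Plot a flow state
#'
#' Raster of velocity magnitude, pressure or flow age on the solver grid.
#'
#' @param object A `flow_state`.
#' @param field `"speed"`, `"pressure"` or `"age"`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.flow_state <- function(object, field = c("speed", "pressure", "age"),
                                ...) {
  field <- match.arg(field)
  grid <- object$grid
  nx <- grid$nx; ny <- grid$ny
  val <- switch(field,
    speed = sqrt((0.5 * (object$u[1:nx, ] + object$u[2:(nx + 1), ]))^2 +
                   (0.5 * (object$v[, 1:ny] + object$v[, 2:(ny + 1)]))^2),
    pressure = object$p,
    age = object$age)
  val[!object$cell_fluid] <- NA
  df <- tibble(x = rep(grid$xc, times = ny) * MM_PER_M,
               y = rep(grid$yc, each = nx) * MM_PER_M,
               value = as.vector(val))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::coord_equal() +
    ggplot2::scale_fill_viridis_c(na.value = "grey90") +
    ggplot2::labs(x = "x (mm)", y = "y (mm)",
                  fill = switch(field, speed = "|u| (m/s)",
                                pressure = "p (Pa)", age = "age (s)"),
                  title = sprintf("t = %.3f s", object$time)) +
    ggplot2::theme_minimal()
}

#' Plot probe pressure traces of a run
#'
#' @param run A `vimflow_run` with probes.
#' @return A ggplot of gauge pressure vs time per probe.
#' @export
plot_probe_pressures <- function(run) {
  if (nrow(run$probe_series) == 0) abort("run has no probe series")
  ggplot2::ggplot(run$probe_series,
                  ggplot2::aes(x = .data$time, y = .data$pressure,
                               colour = .data$probe)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = "gauge pressure (Pa)", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot the neo-LVOT area profile along the axis
#'
#' @param report A `neolvot_report`.
#' @return A ggplot of free-lumen area vs axial position.
#' @export
plot_neolvot_profile <- function(report) {
  ggplot2::ggplot(report$profile,
                  ggplot2::aes(x = .data$s_mm, y = .data$area_mm2)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = c(180, 200), linetype = "dotted") +
    ggplot2::labs(x = "position along neo-LVOT axis (mm)",
                  y = expression("free-lumen area " (mm^2))) +
    ggplot2::theme_minimal()
}
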