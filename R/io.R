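# Serialization: motion series as JSON/CSV, field snapshots as legacy VTK
# structured grids, probe and wall-sample tables as CSV.

#' Write a motion series to JSON
#'
#' Metadata plus per-frame vertex arrays (mm); round-trips with
#' [read_motion_series_json()].
#'
#' @param series A `motion_series`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_motion_series_json <- function(series, path) {
  obj <- list(
    cycle_duration = series$cycle_duration,
    times = series$times,
    mitral_idx = series$mitral_idx,
    aortic_idx = series$aortic_idx,
    frames = lapply(seq_along(series$times), function(k) {
      list(x = series$xs[, k], y = series$ys[, k])
    }),
    device = if (!is.null(series$device)) {
      list(segments = lapply(series$device$segments, function(sg) {
        list(x = sg[, 1], y = sg[, 2])
      }))
    }
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a motion series from JSON
#'
#' @param path JSON file written by [write_motion_series_json()].
#' @return A `motion_series`.
#' @export
read_motion_series_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  nfr <- length(obj$times)
  xs <- vapply(seq_len(nfr), function(k) obj$frames$x[[k]],
               numeric(length(obj$frames$x[[1]])))
  ys <- vapply(seq_len(nfr), function(k) obj$frames$y[[k]],
               numeric(length(obj$frames$y[[1]])))
  areas <- vapply(seq_len(nfr), function(k) polygon_area(cbind(xs[, k], ys[, k])),
                  numeric(1))
  device <- NULL
  if (!is.null(obj$device)) {
    device <- list(segments = lapply(seq_along(obj$device$segments$x), function(i) {
      cbind(obj$device$segments$x[[i]], obj$device$segments$y[[i]])
    }))
  }
  structure(list(xs = xs, ys = ys, times = obj$times, areas = areas,
                 mitral_idx = obj$mitral_idx, aortic_idx = obj$aortic_idx,
                 cycle_duration = obj$cycle_duration, params = NULL,
                 aux = NULL, device = device),
            class = "motion_series")
}

#' Write per-frame boundary CSV files
#'
#' @param series A `motion_series`.
#' @param dir Output directory.
#' @return Invisibly, the written paths.
#' @export
write_motion_series_csv <- function(series, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- vapply(seq_along(series$times), function(k) {
    p <- file.path(dir, sprintf("frame_%03d.csv", k))
    utils::write.csv(data.frame(vertex = seq_len(nrow(series$xs)),
                                x_mm = series$xs[, k], y_mm = series$ys[, k]),
                     p, row.names = FALSE)
    p
  }, character(1))
  invisible(paths)
}

#' Write a flow snapshot as a legacy VTK structured grid
#'
#' Cell-centred velocity, pressure, age and mask on the solver grid, in the
#' plain-text legacy VTK format readable by ParaView.
#'
#' @param state A `flow_state`.
#' @param path Output `.vtk` path.
#' @return Invisibly, `path`.
#' @export
write_vtk_grid <- function(state, path) {
  grid <- state$grid
  nx <- grid$nx; ny <- grid$ny
  uc <- 0.5 * (state$u[1:nx, ] + state$u[2:(nx + 1), ])
  vc <- 0.5 * (state$v[, 1:ny] + state$v[, 2:(ny + 1)])
  con <- file(path, "wt")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               sprintf("vimflow snapshot t=%.6f", state$time),
               "ASCII", "DATASET STRUCTURED_POINTS",
               sprintf("DIMENSIONS %d %d 1", nx, ny),
               sprintf("ORIGIN %g %g 0", grid$xc[1], grid$yc[1]),
               sprintf("SPACING %g %g 1", grid$h, grid$h),
               sprintf("POINT_DATA %d", nx * ny)), con)
  writeLines("VECTORS velocity double", con)
  vel <- cbind(as.vector(uc), as.vector(vc), 0)
  writeLines(apply(vel, 1, function(r) paste(format(r, digits = 9), collapse = " ")), con)
  scalar <- function(name, M) {
    writeLines(c(sprintf("SCALARS %s double 1", name), "LOOKUP_TABLE default"), con)
    writeLines(format(as.vector(M), digits = 9), con)
  }
  scalar("pressure", state$p)
  scalar("age", state$age)
  scalar("mask", state$cell_fluid + 0)
  invisible(path)
}

#' Write probe and wall-sample series as CSV
#'
#' @param run A `vimflow_run`.
#' @param dir Output directory.
#' @return Invisibly, the written paths.
#' @export
write_run_csv <- function(run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p1 <- file.path(dir, "probe_pressures.csv")
  utils::write.csv(run$probe_series, p1, row.names = FALSE)
  p2 <- file.path(dir, "wall_shear.csv")
  utils::write.csv(run$wall_series, p2, row.names = FALSE)
  p3 <- file.path(dir, "fluxes.csv")
  utils::write.csv(run$fluxes, p3, row.names = FALSE)
  invisible(c(p1, p2, p3))
}

#' Write a metrics report as JSON
#'
#' @param report A `metrics_report`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_metrics_json <- function(report, path) {
  obj <- list(
    table = as.list(setNames(tidy(report)$value, tidy(report)$metric)),
    lvoto_class = report$lvoto_class,
    activation_flag = report$activation$flag,
    activation_margin = report$activation$margin,
    wss_threshold_pa = report$wss_threshold,
    exposure_s = report$exposure_s,
    systole_window = report$systole_window,
    cycle_duration = report$cycle_duration,
    n_cycles = report$n_cycles)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Write a displacement field to JSON
#'
#' @param field A `displacement_field`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_displacement_field_json <- function(field, path) {
  jsonlite::write_json(list(origin = field$origin, spacing = field$spacing,
                            dims = dim(field$dx),
                            dx = as.vector(field$dx), dy = as.vector(field$dy)),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a displacement field from JSON
#'
#' @param path JSON path from [write_displacement_field_json()].
#' @return A `displacement_field`.
#' @export
read_displacement_field_json <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  displacement_field(o$origin, o$spacing,
                     matrix(o$dx, o$dims[1], o$dims[2]),
                     matrix(o$dy, o$dims[1], o$dims[2]))
}
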