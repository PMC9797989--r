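# Clinical haemodynamic metrics from solver output: systolic LVOT pressure
# gradients, wall-shear statistics and oscillatory shear index on the device
# frame, platelet-activation exposure time, blood residence time, and the
# obstruction / activation classification rules.

#' Wall-shear record on the device frame
#'
#' Reshapes a long wall-sample table (from [run_cycles()]) into matrices of
#' shear components per sample site over time.
#'
#' @param wall_series Tibble with `time`, `segment`, `side`, `s_mm`, `tau_x`,
#'   `tau_y`.
#' @param systole_window Length-2 numeric, the systolic interval (s).
#' @return A `wss_record`: `times`, per-site `tau_x`, `tau_y` matrices
#'   (site x time), site table, and the systole window.
#' @export
wss_record <- function(wall_series, systole_window) {
  if (nrow(wall_series) == 0) abort("empty wall series")
  key <- paste(wall_series$segment, wall_series$side, wall_series$s_mm)
  sites <- !duplicated(key)
  site_tbl <- wall_series[sites, c("segment", "side", "s_mm")]
  times <- sort(unique(wall_series$time))
  n_s <- sum(sites)
  ord <- order(match(key, key[sites]), wall_series$time)
  tau_x <- matrix(wall_series$tau_x[ord], n_s, length(times), byrow = TRUE)
  tau_y <- matrix(wall_series$tau_y[ord], n_s, length(times), byrow = TRUE)
  structure(list(times = times, tau_x = tau_x, tau_y = tau_y,
                 sites = site_tbl, systole_window = systole_window),
            class = "wss_record")
}

#' @export
print.wss_record <- function(x, ...) {
  cat(sprintf("<wss_record> %d sites x %d samples, |tau| max %.3g Pa\n",
              nrow(x$tau_x), ncol(x$tau_x),
              max(sqrt(x$tau_x^2 + x$tau_y^2))))
  invisible(x)
}

#' @export
as_tibble.wss_record <- function(x, ...) {
  n_s <- nrow(x$tau_x)
  tibble(site = rep(seq_len(n_s), times = length(x$times)),
         time = rep(x$times, each = n_s),
         tau_x = as.vector(x$tau_x), tau_y = as.vector(x$tau_y))
}

in_window <- function(times, win) times >= win[1] & times <= win[2]

record_subset <- function(record, cols) {
  record$times <- record$times[cols]
  record$tau_x <- record$tau_x[, cols, drop = FALSE]
  record$tau_y <- record$tau_y[, cols, drop = FALSE]
  record
}

# wrap times into [win1, win1 + cycle) before applying a within-cycle window
wrap_times <- function(t, win, cycle_duration = NULL) {
  if (is.null(cycle_duration)) return(t)
  ((t - win[1]) %% cycle_duration) + win[1]
}

systole_cols <- function(record, cycle_duration = NULL) {
  tw <- wrap_times(record$times, record$systole_window, cycle_duration)
  in_window(tw, record$systole_window)
}

#' Systolic LVOT pressure gradient from probe series
#'
#' The instantaneous gradient is `p(VC_proximal) - p(VC_distal)`; maximum and
#' time-mean are taken over the systolic window and converted to mmHg
#' (1 mmHg = 133.322 Pa).
#'
#' @param probe_series Tibble with `time`, `probe`, `pressure` (Pa).
#' @param systole_window Length-2 numeric (s); times are wrapped into the
#'   cycle when `cycle_duration` is given.
#' @param cycle_duration Cycle length (s), optional.
#' @return Tibble with `max_mmHg` and `mean_mmHg` (time-mean, trapezoidal).
#' @export
pressure_gradient_lvot <- function(probe_series, systole_window,
                                   cycle_duration = NULL) {
  wide <- tidyr::pivot_wider(probe_series, id_cols = "time",
                             names_from = "probe", values_from = "pressure")
  if (!all(c("VC_proximal", "VC_distal") %in% names(wide))) {
    abort("probe series must contain VC_proximal and VC_distal")
  }
  t <- wide$time
  tw <- wrap_times(t, systole_window, cycle_duration)
  sel <- in_window(tw, systole_window)
  if (!any(sel)) abort("empty systolic window")
  pg <- (wide$VC_proximal - wide$VC_distal)[sel]
  ts <- t[sel]
  mx <- max(pg)
  mn <- if (is.null(cycle_duration) && length(pg) > 1) {
    # contiguous single-cycle window: trapezoidal time-mean
    sum(diff(ts) * (head(pg, -1) + tail(pg, -1)) / 2) / (max(ts) - min(ts))
  } else {
    # uniformly sampled (possibly wrapped multi-cycle) window: sample mean
    mean(pg)
  }
  tibble(max_mmHg = mx / PA_PER_MMHG, mean_mmHg = mn / PA_PER_MMHG)
}

#' Oscillatory shear index per sample site
#'
#' `OSI = 0.5 * (1 - ||int tau dt|| / int ||tau|| dt)` over the record:
#' 0 for shear of time-constant direction, 0.5 for shear whose time average
#' vanishes while its magnitude does not. Sites with identically zero shear
#' are reported as 0 with a flag.
#'
#' @param record A [wss_record()] spanning at least one full cycle.
#' @return Tibble with `site`, `osi` in \[0, 0.5\] and `zero_shear` flag.
#' @export
osi <- function(record) {
  t <- record$times
  if (length(t) < 2) abort("OSI needs at least two time samples")
  w <- trapezoid_weights(t)
  ix <- record$tau_x %*% w
  iy <- record$tau_y %*% w
  mag <- sqrt(record$tau_x^2 + record$tau_y^2) %*% w
  zero <- as.vector(mag) <= .Machine$double.eps
  val <- ifelse(zero, 0, 0.5 * (1 - sqrt(ix^2 + iy^2) / mag))
  val <- pmin(pmax(as.vector(val), 0), 0.5)
  tibble(site = seq_len(nrow(record$tau_x)), osi = val, zero_shear = zero)
}

trapezoid_weights <- function(t) {
  n <- length(t)
  w <- numeric(n)
  dt <- diff(t)
  w[1] <- dt[1] / 2
  w[n] <- dt[n - 1] / 2
  if (n > 2) w[2:(n - 1)] <- (dt[-1] + dt[-(n - 1)]) / 2
  w
}

#' Wall shear stress statistics on the device frame
#'
#' All statistics are taken over the systolic (ejection) window, where the
#' outflow jet loads the frame: `max` is the largest shear magnitude over
#' sites and systolic instants, `mean` the average over sites and systolic
#' samples, `max_surface_averaged` the largest (over systolic instants)
#' arc-length-weighted spatial mean of the magnitude. The leaflet-free frame
#' model lets the diastolic inflow plug shear the frame interior directly, a
#' loading the real leaflet-bearing device does not see, so diastole is
#' excluded.
#'
#' @param record A [wss_record()].
#' @param cycle_duration Cycle length (s) used to wrap multi-cycle records
#'   into the systolic window; optional.
#' @return Tibble with `max_wss`, `mean_wss`, `max_surface_avg_wss` (Pa).
#' @export
wss_statistics <- function(record, cycle_duration = NULL) {
  mag <- sqrt(record$tau_x^2 + record$tau_y^2)
  sel <- systole_cols(record, cycle_duration)
  if (!any(sel)) sel <- rep(TRUE, length(record$times))
  mag_s <- mag[, sel, drop = FALSE]
  # uniform site weights: the frame samples are equally spaced in arc length
  surf <- colMeans(mag_s)
  tibble(max_wss = max(mag_s),
         mean_wss = mean(mag_s),
         max_surface_avg_wss = max(surf))
}

#' Platelet-activation exposure time
#'
#' The measure (sum of time-step lengths) of instants at which the spatial
#' maximum of the shear magnitude exceeds the threshold.
#'
#' @param record A [wss_record()].
#' @param threshold Activation threshold (Pa, > 0).
#' @return Exposure time (s), between 0 and the record duration.
#' @export
exposure_time <- function(record, threshold) {
  if (threshold <= 0) abort("`threshold` must be positive")
  mag_max <- apply(sqrt(record$tau_x^2 + record$tau_y^2), 2, max)
  if (length(record$times) < 2) return(0)
  # uniformly sampled records (possibly with gaps after windowing): one time
  # step of exposure per exceeding sample
  dt <- stats::median(diff(record$times))
  dt * sum(mag_max > threshold)
}

#' Literature-style platelet-activation threshold curve
#'
#' Pairs of (exposure time, shear magnitude) above which platelet activation
#' is expected, interpolated log-log. The packaged default is a synthetic
#' configuration curve shaped like published shear--exposure activation loci
#' (roughly constant stress-time product); it is a placeholder to be replaced
#' with literature values by the user, and is tagged as such.
#'
#' @param points Data frame with `exposure_s`, `wss_pa` and optionally
#'   `citation_tag`; `NULL` loads the packaged synthetic curve.
#' @return An `activation_curve` (tibble sorted by exposure).
#' @export
activation_curve <- function(points = NULL) {
  if (is.null(points)) {
    path <- system.file("extdata", "activation_thresholds_synthetic.csv",
                        package = "vimflow")
    points <- utils::read.csv(path, comment.char = "#")
  }
  stopifnot(all(c("exposure_s", "wss_pa") %in% names(points)))
  if (any(points$wss_pa <= 0) || any(points$exposure_s <= 0)) {
    abort("activation curve points must be positive")
  }
  points <- points[order(points$exposure_s), ]
  structure(as_tibble(points), class = c("activation_curve", class(as_tibble(points))))
}

#' Interpolate the activation threshold at an exposure time
#'
#' Log-log linear interpolation; exposures outside the curve range use the
#' nearest endpoint with a warning.
#'
#' @param curve An [activation_curve()].
#' @param exposure Exposure time (s).
#' @return Threshold shear magnitude (Pa).
#' @export
activation_threshold_at <- function(curve, exposure) {
  le <- log(curve$exposure_s); lw <- log(curve$wss_pa)
  if (exposure <= 0) abort("`exposure` must be positive")
  if (exposure < min(curve$exposure_s) || exposure > max(curve$exposure_s)) {
    warn("exposure outside the threshold curve range; using nearest endpoint")
    exposure <- min(max(exposure, min(curve$exposure_s)), max(curve$exposure_s))
  }
  exp(approx(le, lw, xout = log(exposure), rule = 2)$y)
}

#' Compare a run's shear exposure against an activation threshold curve
#'
#' @param max_wss Maximum wall shear magnitude (Pa).
#' @param exposure Exposure time (s).
#' @param curve An [activation_curve()].
#' @return Tibble with `flag` (`"above"`/`"below"`), `margin`
#'   (`max_wss / threshold`) and the interpolated `threshold`.
#' @export
activation_check <- function(max_wss, exposure, curve = activation_curve()) {
  if (nrow(curve) == 0) abort("empty activation curve")
  thr <- activation_threshold_at(curve, exposure)
  tibble(flag = if (max_wss >= thr) "above" else "below",
         margin = max_wss / thr, threshold = thr)
}

#' Blood residence time statistics
#'
#' Statistics of the flow-age field in a region at the end of a run.
#'
#' @param state A `flow_state` after at least one full cycle.
#' @param region Logical matrix selecting cells (e.g. from
#'   [frame_region_mask()]), or `NULL` for the whole cavity.
#' @param cycle_duration Cycle length (s).
#' @return Tibble with `mean_s`, `mean_cycles`, `max_cycles`.
#' @export
brt_statistics <- function(state, region = NULL, cycle_duration) {
  sel <- state$cell_fluid
  if (!is.null(region)) sel <- sel & region
  if (!any(sel)) abort("empty region for residence-time statistics")
  a <- state$age[sel]
  tibble(mean_s = mean(a), mean_cycles = mean(a) / cycle_duration,
         max_cycles = max(a) / cycle_duration)
}

#' Cell mask of the region inside the device frame
#'
#' @param state A `flow_state`.
#' @param dense A `dense_motion` carrying the embedded device.
#' @return Logical nx x ny matrix.
#' @export
frame_region_mask <- function(state, dense) {
  if (is.null(dense$device)) abort("series has no embedded device")
  segs <- dense$device$segments
  quad <- rbind(segs[[1]][1, ], segs[[1]][2, ], segs[[2]][2, ], segs[[2]][1, ]) / MM_PER_M
  grid <- state$grid
  centers <- cbind(rep(grid$xc, times = grid$ny), rep(grid$yc, each = grid$nx))
  matrix(points_in_polygon(centers, ensure_ccw(quad)), grid$nx, grid$ny)
}

#' Post-procedural LVOT obstruction classification
#'
#' Obstruction is excessive when the peak systolic LVOT gradient exceeds
#' 50 mmHg, or when it has risen by 10 mmHg or more over the pre-procedural
#' baseline ("greater than 50" strict, "10 or more" inclusive).
#'
#' @param peak_pg Peak systolic LVOT gradient (mmHg, >= 0).
#' @param baseline_pg Pre-procedural baseline gradient (mmHg) or `NULL`.
#' @return `"excessive"` or `"acceptable"`.
#' @export
classify_lvoto <- function(peak_pg, baseline_pg = NULL) {
  if (any(!is.finite(peak_pg)) || any(peak_pg < 0)) {
    abort("`peak_pg` must be non-negative")
  }
  if (!is.null(baseline_pg) && any(baseline_pg < 0)) {
    abort("`baseline_pg` must be non-negative")
  }
  exc <- peak_pg > 50
  if (!is.null(baseline_pg)) exc <- exc | (peak_pg - baseline_pg >= 10)
  unname(ifelse(exc, "excessive", "acceptable"))
}

#' Full metrics report for a run
#'
#' Computes the clinical summary from a [run_cycles()] result: systolic LVOT
#' pressure gradients, wall-shear statistics and OSI on the device frame,
#' platelet-activation exposure, blood residence time inside the frame and
#' over the whole cavity, and the classification flags.
#'
#' @param run A `vimflow_run` with probes and a device.
#' @param curve An [activation_curve()].
#' @param wss_threshold Platelet-activation shear threshold used for the
#'   exposure time (Pa); defaults to the curve value at one systole.
#' @param baseline_pg Optional pre-procedural baseline gradient (mmHg).
#' @return A `metrics_report` object.
#' @export
metrics_report <- function(run, curve = activation_curve(),
                           wss_threshold = NULL, baseline_pg = NULL) {
  stopifnot(inherits(run, "vimflow_run"))
  tc <- run$cycle_duration
  pg <- pressure_gradient_lvot(run$probe_series, run$systole_window, tc)
  rec <- wss_record(run$wall_series, run$systole_window)
  ws <- wss_statistics(rec, tc)
  if (is.null(wss_threshold)) {
    systole_len <- diff(run$systole_window)
    wss_threshold <- activation_threshold_at(curve, systole_len)
  }
  # exposure counted over systolic instants (the ejection jet is what loads
  # the frame; cf. the systole-window choice in wss_statistics), keeping
  # exposure <= systole duration x n_cycles
  rec_sys <- record_subset(rec, systole_cols(rec, tc))
  expo <- exposure_time(rec_sys, wss_threshold)
  os <- osi(rec)
  act <- activation_check(ws$max_wss, max(expo, 1e-4), curve)
  brt_cavity <- brt_statistics(run$state, NULL, tc)
  brt_frame <- if (!is.null(run$dense$device)) {
    brt_statistics(run$state, frame_region_mask(run$state, run$dense), tc)
  } else NULL
  structure(list(
    pg = pg, wss = ws, exposure_s = expo, wss_threshold = wss_threshold,
    osi = os, brt_cavity = brt_cavity, brt_frame = brt_frame,
    lvoto_class = classify_lvoto(pg$max_mmHg, baseline_pg),
    baseline_pg = baseline_pg,
    activation = act, systole_window = run$systole_window,
    cycle_duration = tc, n_cycles = run$n_cycles
  ), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("<metrics_report>\n")
  print(tidy(x), n = 20)
  invisible(x)
}

#' @rdname metrics_report
#' @param x A `metrics_report`.
#' @param ... Unused.
#' @export
tidy.metrics_report <- function(x, ...) {
  rows <- tibble(
    metric = c("Max systolic PG LVOT (mmHg)", "Mean systolic PG LVOT (mmHg)",
               "Max WSS (Pa)", "Exposure time (s)", "Mean WSS (Pa)",
               "Max surface averaged WSS (Pa)",
               "Mean BRT in frame (s)", "Mean BRT in frame (cycles)",
               "Max BRT in frame (cycles)",
               "Mean BRT in cavity (s)", "Max OSI", "Min OSI"),
    value = c(x$pg$max_mmHg, x$pg$mean_mmHg,
              x$wss$max_wss, x$exposure_s, x$wss$mean_wss,
              x$wss$max_surface_avg_wss,
              if (is.null(x$brt_frame)) NA_real_ else x$brt_frame$mean_s,
              if (is.null(x$brt_frame)) NA_real_ else x$brt_frame$mean_cycles,
              if (is.null(x$brt_frame)) NA_real_ else x$brt_frame$max_cycles,
              x$brt_cavity$mean_s, max(x$osi$osi), min(x$osi$osi)))
  rows
}

#' @rdname metrics_report
#' @export
glance.metrics_report <- function(x, ...) {
  tibble(max_pg_mmHg = x$pg$max_mmHg, mean_pg_mmHg = x$pg$mean_mmHg,
         max_wss_pa = x$wss$max_wss, exposure_s = x$exposure_s,
         lvoto_class = x$lvoto_class, activation_flag = x$activation$flag,
         activation_margin = x$activation$margin)
}
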