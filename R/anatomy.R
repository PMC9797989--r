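# Synthetic 2D long-axis left-ventricle anatomy with prescribed periodic wall
# motion. Stands in for segmented multiphase CT: each frame is a closed
# boundary polyline with labeled mitral and aortic orifice segments and a
# cavity area (the 2D surrogate of the volume curve V(t)).
#
# Geometry convention: x runs septal (negative) to lateral (positive), y runs
# apex (0) to base (long_axis_length). Millimetres throughout. Boundaries are
# counterclockwise.

#' Shape and motion parameters for the idealized left ventricle
#'
#' Lengths are in mm, angles in degrees, times in seconds. The defaults give a
#' ventricle of ordinary adult proportions with a moderate septal bulge. The
#' aortomitral angle is the obtuse angle between the mitral annulus plane and
#' the LVOT axis; values above 90 degrees tilt the outflow channel over the
#' septum.
#'
#' @param long_axis_length Apex-to-base distance (mm).
#' @param basal_diameter Cavity width at the base (mm).
#' @param lvot_width Perpendicular width of the outflow channel (mm).
#' @param septal_bulge_amplitude Protrusion of the basal septum into the
#'   cavity (mm); 0 gives a straight septal wall under the LVOT.
#' @param aortomitral_angle Obtuse angle between annulus plane and LVOT axis
#'   (degrees, open interval 60-180).
#' @param mitral_annulus_diameter Chord length of the mitral orifice (mm).
#' @param ejection_fraction Cavity-area ejection fraction (percent, 0-100
#'   exclusive).
#' @param cycle_duration Cardiac cycle length (s).
#' @param n_frames Number of distinct phases per cycle (3-50; gated cardiac CT
#'   typically reconstructs 10).
#' @param seed Integer seed recorded with the series; the generator is fully
#'   deterministic.
#' @param systole_fraction Fraction of the cycle spent contracting.
#' @param lvot_channel_length Length of the straight outflow channel beyond
#'   the base (mm).
#' @param n_boundary_points Approximate number of boundary vertices.
#' @return An object of class `lv_shape_params`.
#' @export
lv_shape_params <- function(long_axis_length = 80,
                            basal_diameter = 50,
                            lvot_width = 18,
                            septal_bulge_amplitude = 3,
                            aortomitral_angle = 115,
                            mitral_annulus_diameter = 24,
                            ejection_fraction = 45,
                            cycle_duration = 0.8,
                            n_frames = 10,
                            seed = 1L,
                            systole_fraction = 0.38,
                            lvot_channel_length = 14,
                            n_boundary_points = 176) {
  p <- list(
    long_axis_length = long_axis_length, basal_diameter = basal_diameter,
    lvot_width = lvot_width, septal_bulge_amplitude = septal_bulge_amplitude,
    aortomitral_angle = aortomitral_angle,
    mitral_annulus_diameter = mitral_annulus_diameter,
    ejection_fraction = ejection_fraction, cycle_duration = cycle_duration,
    n_frames = as.integer(n_frames), seed = as.integer(seed),
    systole_fraction = systole_fraction,
    lvot_channel_length = lvot_channel_length,
    n_boundary_points = as.integer(n_boundary_points)
  )
  lens <- c("long_axis_length", "basal_diameter", "lvot_width",
            "mitral_annulus_diameter", "cycle_duration", "lvot_channel_length")
  for (nm in lens) {
    if (!is.finite(p[[nm]]) || p[[nm]] <= 0) {
      abort(sprintf("`%s` must be positive (got %s)", nm, p[[nm]]))
    }
  }
  if (p$septal_bulge_amplitude < 0) abort("`septal_bulge_amplitude` must be >= 0")
  if (p$ejection_fraction <= 0 || p$ejection_fraction >= 100) {
    abort("`ejection_fraction` must lie strictly between 0 and 100 percent")
  }
  if (p$n_frames < 3 || p$n_frames > 50) abort("`n_frames` must be in [3, 50]")
  if (p$aortomitral_angle <= 60 || p$aortomitral_angle >= 180) {
    abort("`aortomitral_angle` must lie in (60, 180) degrees")
  }
  # fit of the base layout: lateral margin + annulus + curtain + oblique LVOT
  # inlet must not overrun the septal half of the base
  phi <- (180 - p$aortomitral_angle) * pi / 180
  w_in <- p$lvot_width / sin(phi)
  span <- 2 + p$mitral_annulus_diameter + 2.5 + w_in
  if (span > p$basal_diameter - 1) {
    abort(paste0(
      "geometry does not close: `mitral_annulus_diameter` + `lvot_width` ",
      sprintf("need a base span of %.1f mm but `basal_diameter` is %.1f mm",
              span, p$basal_diameter)
    ))
  }
  if (p$septal_bulge_amplitude > 0.9 * p$lvot_width) {
    abort(paste0("`septal_bulge_amplitude` would occlude the channel set by ",
                 "`lvot_width`; reduce the bulge or widen the channel"))
  }
  structure(p, class = "lv_shape_params")
}

# two-phase contraction waveform: 0 at end-diastole, 1 at end-systole,
# cosine ramps either side, C1-periodic over the cycle
contraction_phase <- function(t, cycle, systole_fraction) {
  t <- t %% cycle
  ts <- systole_fraction * cycle
  ifelse(t <= ts,
         0.5 * (1 - cos(pi * t / ts)),
         0.5 * (1 + cos(pi * (t - ts) / (cycle - ts))))
}

# build the end-diastolic reference boundary; returns list(points, mitral_idx,
# aortic_idx, aux) with counterclockwise orientation
build_reference_boundary <- function(p) {
  L <- p$long_axis_length
  phi <- (180 - p$aortomitral_angle) * pi / 180   # LVOT tilt above horizontal
  u <- c(-cos(phi), sin(phi))                     # channel direction (unit)
  w_in <- p$lvot_width / sin(phi)                 # inlet chord on the base

  xm1 <- p$basal_diameter / 2 - 2                 # annulus lateral end
  xm0 <- xm1 - p$mitral_annulus_diameter          # annulus septal end
  pr <- c(xm0 - 2.5, L)                           # channel right-wall base
  pl <- c(pr[1] - w_in, L)                        # channel left-wall base
  pr_top <- pr + p$lvot_channel_length * u
  pl_top <- pl + p$lvot_channel_length * u

  nb <- p$n_boundary_points
  n_arc <- max(24L, as.integer(round(nb * 0.32)))
  n_mit <- max(8L, as.integer(round(nb * 0.08)))
  n_cur <- 3L
  n_wall <- max(6L, as.integer(round(nb * 0.05)))
  n_ao <- max(6L, as.integer(round(nb * 0.05)))

  arc <- function(x_end, tt) cbind(x_end * sin(tt), L * (1 - cos(tt)))
  t_lat <- seq(0, pi / 2, length.out = n_arc + 1)
  lat <- arc(xm1, t_lat)                          # apex -> (xm1, L)
  t_sep <- seq(pi / 2, 0, length.out = n_arc + 1)
  sep <- arc(pl[1], t_sep)                        # (pl_x, L) -> apex
  # septal bulge protrudes into the cavity (+x) near the base
  yb <- L - 14; sb <- 7
  sep[, 1] <- sep[, 1] + p$septal_bulge_amplitude * exp(-((sep[, 2] - yb) / sb)^2)

  lerp <- function(a, b, n) cbind(seq(a[1], b[1], length.out = n),
                                  seq(a[2], b[2], length.out = n))
  mit <- lerp(c(xm1, L), c(xm0, L), n_mit + 1)
  cur <- lerp(c(xm0, L), pr, n_cur + 1)
  rwall <- lerp(pr, pr_top, n_wall + 1)
  ao <- lerp(pr_top, pl_top, n_ao + 1)
  lwall <- lerp(pl_top, pl, n_wall + 1)

  drop_last <- function(m) m[-nrow(m), , drop = FALSE]
  pieces <- list(lat = drop_last(lat), mit = drop_last(mit),
                 cur = drop_last(cur), rwall = drop_last(rwall),
                 ao = drop_last(ao), lwall = drop_last(lwall),
                 sep = drop_last(sep))
  pts <- do.call(rbind, pieces)
  offs <- cumsum(c(0, vapply(pieces, nrow, integer(1))))
  names(offs) <- c(names(pieces), "end")
  # index ranges include both endpoints of each orifice chord; each piece
  # excludes its final vertex, so piece k starts at offs[[k]] + 1
  mitral_idx <- (offs[["mit"]] + 1L):(offs[["cur"]] + 1L)  # (xm1,L) .. (xm0,L)
  aortic_idx <- (offs[["ao"]] + 1L):(offs[["lwall"]] + 1L) # pr_top .. pl_top
  rownames(pts) <- NULL

  if (!polygon_is_simple(pts)) {
    abort(paste0("generated boundary self-intersects; the `lvot_width` / ",
                 "`septal_bulge_amplitude` pair is inconsistent with the ",
                 "basal layout"))
  }
  if (polygon_area(pts) <= 0) abort("internal: boundary orientation flipped")
  list(points = pts, mitral_idx = as.integer(mitral_idx),
       aortic_idx = as.integer(aortic_idx),
       aux = list(u = u, annulus = c(xm0, xm1), pl = pl, pr = pr,
                  pl_top = pl_top, pr_top = pr_top, piece_offsets = offs))
}

# displacement model: points move toward a contraction centre with a weight
# that vanishes at the base and in the channel, scaled to hit a target area
deform_boundary <- function(pts, kappa, centre, weight) {
  pts + kappa * weight * (cbind(centre[1] - pts[, 1], centre[2] - pts[, 2]))
}

# basal pinning: the annulus, curtain and outflow channel do not move, and the
# basal region moves little, concentrating contraction at the mid-cavity and
# apex. `pin_depth` is how far below the base the motion ramp starts.
motion_weight <- function(pts, L, pin_depth = 18, ramp = 24) {
  smoothstep(((L - pin_depth) - pts[, 2]) / ramp)
}

#' Generate an idealized moving-wall left ventricle
#'
#' Builds a closed 2D long-axis boundary with a bulged septal wall, an oblique
#' LVOT channel and labeled mitral/aortic orifice segments, then prescribes
#' periodic wall motion: boundary points contract toward a mid-ventricular
#' centre with a basally pinned weight, with the per-frame amplitude solved so
#' the cavity area follows a smooth two-phase systole-diastole waveform at the
#' requested ejection fraction.
#'
#' @param params An [lv_shape_params()] object.
#' @return A `motion_series` object: frames at `n_frames + 1` times spanning
#'   one cycle (the last frame duplicates the first), boundary vertex arrays,
#'   orifice index ranges and per-frame cavity areas (mm^2).
#' @export
generate_anatomy <- function(params) {
  stopifnot(inherits(params, "lv_shape_params"))
  ref <- build_reference_boundary(params)
  pts0 <- ref$points
  L <- params$long_axis_length
  centre <- c(0, 0.6 * L)
  a0 <- polygon_area(pts0)
  ef <- params$ejection_fraction / 100
  # choose the shallowest basal pinning able to reach end-systolic area; high
  # ejection fractions recruit more basal wall motion
  w <- NULL
  for (dr in list(c(18, 24), c(12, 20), c(8, 14), c(5, 10), c(3, 6))) {
    wd <- motion_weight(pts0, L, dr[1], dr[2])
    if (polygon_area(deform_boundary(pts0, 0.97, centre, wd)) <= a0 * (1 - ef)) {
      w <- wd
      break
    }
  }
  if (is.null(w)) {
    abort(paste0("`ejection_fraction` is unreachable for this geometry: the ",
                 "pinned basal region retains more area than the end-systolic ",
                 "target allows"))
  }

  times <- seq(0, params$cycle_duration, length.out = params$n_frames + 1L)
  s <- contraction_phase(times, params$cycle_duration, params$systole_fraction)
  # normalize so the sampled end-systolic frame hits the requested ejection
  # fraction exactly even when the frame grid misses the waveform peak
  s <- s / max(s)

  n_pts <- nrow(pts0)
  xs <- matrix(0, n_pts, length(times))
  ys <- matrix(0, n_pts, length(times))
  areas <- numeric(length(times))
  for (k in seq_along(times)) {
    target <- a0 * (1 - ef * s[k])
    if (s[k] < 1e-12) {
      pk <- pts0
    } else {
      f <- function(kap) polygon_area(deform_boundary(pts0, kap, centre, w)) - target
      kap <- uniroot(f, c(0, 0.98), tol = 1e-12)$root
      pk <- deform_boundary(pts0, kap, centre, w)
    }
    xs[, k] <- pk[, 1]; ys[, k] <- pk[, 2]
    areas[k] <- polygon_area(pk)
  }
  ratio <- min(areas) / max(areas)
  if (abs(ratio - (1 - ef)) > 0.01) {
    abort("internal: cavity-area waveform missed the requested ejection fraction")
  }
  for (k in seq_along(times)) {
    if (!polygon_is_simple(cbind(xs[, k], ys[, k]))) {
      abort(sprintf(paste0("wall motion self-intersects the boundary at frame ",
                           "%d; `septal_bulge_amplitude` and `ejection_fraction` ",
                           "are inconsistent"), k))
    }
  }
  structure(list(
    xs = xs, ys = ys, times = times, areas = areas,
    mitral_idx = ref$mitral_idx, aortic_idx = ref$aortic_idx,
    cycle_duration = params$cycle_duration, params = params,
    aux = ref$aux, device = NULL
  ), class = "motion_series")
}

#' @export
print.motion_series <- function(x, ...) {
  cat(sprintf(
    "<motion_series> %d boundary points, %d frames over %.3g s cycle\n",
    nrow(x$xs), length(x$times), x$cycle_duration))
  cat(sprintf("  cavity area %.0f-%.0f mm^2 (EF %.1f%%)%s\n",
              min(x$areas), max(x$areas),
              100 * (1 - min(x$areas) / max(x$areas)),
              if (is.null(x$device)) "" else ", device embedded"))
  invisible(x)
}

#' Boundary of one frame of a motion series
#'
#' @param series A `motion_series`.
#' @param frame 1-based frame index.
#' @return n x 2 matrix of boundary vertices (mm).
#' @export
frame_boundary <- function(series, frame = 1L) {
  cbind(series$xs[, frame], series$ys[, frame])
}

#' Per-frame cavity areas
#'
#' @param series A `motion_series`.
#' @return Tibble with `frame`, `time` (s) and `area` (mm^2).
#' @export
cavity_areas <- function(series) {
  tibble(frame = seq_along(series$times), time = series$times,
         area = series$areas)
}

#' @export
as_tibble.motion_series <- function(x, ...) {
  series <- x
  n <- nrow(series$xs)
  purrr::map_dfr(seq_along(series$times), function(k) {
    tibble(frame = k, time = series$times[k], vertex = seq_len(n),
           x = series$xs[, k], y = series$ys[, k])
  })
}

#' Specification of the bioprosthetic frame cross-section
#'
#' The device is a leaflet-free open frame: in the 2D long-axis plane it is
#' represented by two rigid straight segments anchored at the mitral annulus
#' and extending into the ventricle along the device axis. `protrusion_fraction`
#' tilts the axis toward the LVOT, moving the septal-side frame wall into the
#' outflow channel (the mechanism that narrows the neo-LVOT).
#'
#' @param diameter Frame diameter (mm).
#' @param height Frame height (mm).
#' @param center Annulus-level centre of the frame (2D point, mm); defaults to
#'   the mitral annulus midpoint when embedded.
#' @param axis Unit 2D vector of the frame axis; computed from
#'   `protrusion_fraction` when `NULL`.
#' @param protrusion_fraction In \[0, 1\]; 0 leaves the frame hanging straight
#'   below the annulus, 1 tilts it by `max_tilt` degrees toward the LVOT.
#' @param max_tilt Tilt at `protrusion_fraction = 1` (degrees).
#' @return A `valve_frame_spec` object.
#' @export
valve_frame_spec <- function(diameter = 20, height = 16, center = NULL,
                             axis = NULL, protrusion_fraction = 0,
                             max_tilt = 32) {
  if (diameter <= 0 || height <= 0) abort("`diameter` and `height` must be positive")
  if (protrusion_fraction < 0 || protrusion_fraction > 1) {
    abort("`protrusion_fraction` must lie in [0, 1]")
  }
  if (!is.null(axis)) {
    nrm <- sqrt(sum(axis^2))
    if (abs(nrm - 1) > 1e-8) abort("`axis` must have unit norm")
  }
  structure(list(diameter = diameter, height = height, center = center,
                 axis = axis, protrusion_fraction = protrusion_fraction,
                 max_tilt = max_tilt),
            class = "valve_frame_spec")
}

# the two frame segments implied by a spec anchored at a given annulus chord;
# returns list of two 2 x 2 matrices (rows: anchor, tip)
frame_segments <- function(spec, annulus_mid) {
  center <- spec$center %||% annulus_mid
  theta <- spec$protrusion_fraction * spec$max_tilt * pi / 180
  axis <- spec$axis %||% c(-sin(theta), -cos(theta))  # into the cavity, tilted septally
  half <- spec$diameter / 2
  anchors <- rbind(center - c(half, 0), center + c(half, 0))
  lapply(1:2, function(i) {
    rbind(anchors[i, ], anchors[i, ] + spec$height * axis)
  })
}

#' Embed the bioprosthetic frame in a motion series
#'
#' Anchors the two rigid frame segments at the mitral annulus. The annulus is
#' pinned by the wall-motion model, so the frame is stationary both in the
#' annulus frame of reference and in the laboratory frame. Every cardiac phase
#' is checked: a frame wall crossing the endocardial boundary is an error.
#'
#' @param series A `motion_series`.
#' @param spec A [valve_frame_spec()].
#' @return The series with a `device` element (spec plus segment coordinates).
#' @export
embed_valve <- function(series, spec) {
  stopifnot(inherits(series, "motion_series"), inherits(spec, "valve_frame_spec"))
  ann <- series$aux$annulus
  annulus_mid <- c(mean(ann), series$params$long_axis_length)
  segs <- frame_segments(spec, annulus_mid)
  # sample along each segment, excluding the annulus anchor which lies on the
  # boundary by construction
  tt <- seq(0.06, 1, length.out = 16)
  samp <- do.call(rbind, lapply(segs, function(sg) {
    cbind(sg[1, 1] + tt * (sg[2, 1] - sg[1, 1]),
          sg[1, 2] + tt * (sg[2, 2] - sg[1, 2]))
  }))
  bad <- integer(0)
  for (k in seq_along(series$times)) {
    b <- frame_boundary(series, k)
    ok <- points_in_polygon(samp, b)
    if (!all(ok)) {
      # a frame sized to the annulus grazes the boundary at the anchors;
      # allow sub-resolution contact
      d <- dist_points_to_polyline(samp[!ok, , drop = FALSE],
                                   rbind(b, b[1, ]))
      if (any(d > 0.3)) bad <- c(bad, k)
    }
  }
  if (length(bad) > 0) {
    abort(sprintf("valve frame intersects the endocardial boundary at phase(s) %s",
                  paste(bad, collapse = ", ")))
  }
  series$device <- list(spec = spec, segments = segs, annulus_mid = annulus_mid)
  series
}

#' Minimal neo-LVOT channel width of an embedded series
#'
#' Brute-force minimal distance between the septal-side frame wall (or, with
#' no device, the channel right wall) and the septal boundary chain, i.e. the
#' 2D analogue of the narrowest neo-LVOT cross-section.
#'
#' @param series A `motion_series` (device optional).
#' @param frame Frame index at which to measure.
#' @param n_samples Samples along each wall for the brute-force search.
#' @return Width in mm.
#' @export
measure_channel_width <- function(series, frame = 1L, n_samples = 250) {
  bnd <- frame_boundary(series, frame)
  # septal chain: left channel wall + septal arc (from aortic segment end on)
  i0 <- max(series$aortic_idx)
  sep_chain <- bnd[i0:nrow(bnd), , drop = FALSE]
  if (!is.null(series$device)) {
    seg <- series$device$segments[[1]]      # septal-side frame wall
    right <- resample_chain(seg, n_samples)
  } else {
    # unobstructed: the channel's own right wall
    j0 <- max(series$mitral_idx) + 1L
    j1 <- min(series$aortic_idx)
    right <- resample_chain(bnd[j0:j1, , drop = FALSE], n_samples)
  }
  min(dist_points_to_polyline(right, resample_chain(sep_chain, n_samples)))
}
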