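# Cardiac-cycle runs: probe pressure series, wall shear sampling on the
# device frame, flux bookkeeping and field snapshots.

#' Pressure probe set
#'
#' Standard probe placement: mitral valve (MV), aortic valve (AV), apex (AP),
#' and two probes 5 mm proximal and distal of the vena contracta between the
#' device frame and the septal wall. Pressures sampled at these probes are
#' referenced to the AV probe.
#'
#' @param series A `motion_series` with an embedded device (for the vena
#'   contracta) or without (probes straddle the channel inlet instead).
#' @param vc_offset Offset of the vena-contracta probes (mm).
#' @return A `probe_set`: tibble with `probe`, `x`, `y` (mm).
#' @export
probe_set <- function(series, vc_offset = 5) {
  stopifnot(inherits(series, "motion_series"))
  L <- series$params$long_axis_length
  aux <- series$aux
  b <- frame_boundary(series, 1L)
  ann_mid <- c(mean(aux$annulus), L)
  ao_mid <- 0.5 * (aux$pl_top + aux$pr_top)
  u <- aux$u
  mv <- ann_mid + c(0, -7)
  av <- ao_mid - 4 * u
  # apical probe: just above the most-contracted apex position
  apex_y <- max(vapply(seq_along(series$times),
                       function(k) min(series$ys[, k]), numeric(1)))
  ap <- c(0, apex_y + 6)
  if (!is.null(series$device)) {
    seg <- series$device$segments[[1]]
    segp <- resample_chain(seg, 200)
    i0 <- max(series$aortic_idx)
    sep_chain <- resample_chain(b[i0:nrow(b), , drop = FALSE], 400)
    d2 <- outer(rowSums(segp^2), rowSums(sep_chain^2), "+") - 2 * segp %*% t(sep_chain)
    k <- arrayInd(which.min(d2), dim(d2))
    vc <- 0.5 * (segp[k[1], ] + sep_chain[k[2], ])
  } else {
    vc <- 0.5 * (aux$pl + aux$pr)
  }
  vcp <- vc - vc_offset * u   # proximal: upstream, inside the ventricle
  vcd <- vc + vc_offset * u   # distal: downstream, toward the outlet
  probes <- tibble(probe = c("MV", "AV", "AP", "VC_proximal", "VC_distal"),
                   x = c(mv[1], av[1], ap[1], vcp[1], vcd[1]),
                   y = c(mv[2], av[2], ap[2], vcp[2], vcd[2]))
  # every probe must stay inside the cavity (and off the device) at all phases
  for (k in seq_along(series$times)) {
    ok <- points_in_polygon(as.matrix(probes[, c("x", "y")]),
                            frame_boundary(series, k))
    if (!is.null(series$device)) {
      for (sg in series$device$segments) {
        ok <- ok & (dist_points_to_segment(as.matrix(probes[, c("x", "y")]),
                                           sg[1, ], sg[2, ]) > 1)
      }
    }
    if (!all(ok)) {
      abort(sprintf("probe(s) %s fall outside the fluid region at phase %d",
                    paste(probes$probe[!ok], collapse = ", "), k))
    }
  }
  structure(probes, class = c("probe_set", class(probes)))
}

#' Sample gauge pressures at probes
#'
#' Bilinear interpolation of the cell-centred pressure, referenced to the AV
#' probe (the solver pressure is defined up to a constant).
#'
#' @param state A `flow_state`.
#' @param probes A [probe_set()] (mm coordinates).
#' @return Tibble with `probe` and `pressure` (Pa, gauge vs AV).
#' @export
sample_probe_pressure <- function(state, probes) {
  grid <- state$grid
  xm <- probes$x / MM_PER_M; ym <- probes$y / MM_PER_M
  ci <- pmin(pmax(ceiling((xm - grid$origin[1]) / grid$h), 1), grid$nx)
  cj <- pmin(pmax(ceiling((ym - grid$origin[2]) / grid$h), 1), grid$ny)
  infl <- state$cell_fluid[cbind(ci, cj)]
  if (!all(infl)) {
    abort(sprintf("probe(s) %s lie in solid cells at t = %.4f s",
                  paste(probes$probe[!infl], collapse = ", "), state$time))
  }
  p <- sample_staggered(state$p, xm, ym, grid, "p")
  ref <- p[probes$probe == "AV"]
  if (length(ref) == 0) ref <- 0
  tibble(probe = probes$probe, pressure = p - ref)
}

# two-point one-sided wall shear (exact for quadratic profiles):
# tau = mu * (4 u_t(h) - u_t(2h)) / (2h), sampled along +normal from the wall
wall_shear_probe <- function(state, pts_m, normal, tangent, mu) {
  grid <- state$grid
  h <- grid$h
  p1 <- pts_m + h * matrix(normal, nrow(pts_m), 2, byrow = TRUE)
  p2 <- pts_m + 2 * h * matrix(normal, nrow(pts_m), 2, byrow = TRUE)
  ut <- function(P) {
    uu <- sample_staggered(state$u, P[, 1], P[, 2], grid, "u")
    vv <- sample_staggered(state$v, P[, 1], P[, 2], grid, "v")
    uu * tangent[1] + vv * tangent[2]
  }
  mu * (4 * ut(p1) - ut(p2)) / (2 * h)
}

# WSS samples along both sides of each device frame segment. The frame is a
# one-cell-thick immersed band, so the velocity is sampled at 1.5h and 2.5h
# off the segment midline (outside the band) and the wall gradient taken by a
# quadratic fit through zero at the effective wall surface (the band edge at
# 0.55h); this keeps the stencil clear of solid-contaminated bilinear samples
# for tilted segments.
device_wall_shear <- function(state, device_segments_m, mu) {
  grid <- state$grid
  h <- grid$h
  w0 <- 0.55 * h
  o1 <- 1.5 * h; o2 <- 2.5 * h
  d1 <- o1 - w0; d2 <- o2 - w0
  out <- list()
  for (si in seq_along(device_segments_m)) {
    sg <- device_segments_m[[si]]
    d <- sg[2, ] - sg[1, ]
    len <- sqrt(sum(d^2))
    tangent <- d / len
    nrm <- c(-tangent[2], tangent[1])
    n_s <- max(4L, floor(len / h))
    tt <- seq(0.08, 0.92, length.out = n_s)
    pts <- cbind(sg[1, 1] + tt * d[1], sg[1, 2] + tt * d[2])
    ut_at <- function(off, side) {
      P <- pts + side * off * matrix(nrm, nrow(pts), 2, byrow = TRUE)
      uu <- sample_staggered(state$u, P[, 1], P[, 2], grid, "u")
      vv <- sample_staggered(state$v, P[, 1], P[, 2], grid, "v")
      list(ut = uu * tangent[1] + vv * tangent[2], P = P)
    }
    for (side in c(1, -1)) {
      s1 <- ut_at(o1, side); s2 <- ut_at(o2, side)
      # u(d) = a d + b d^2 with u(0) = 0 at the effective wall
      a <- (s1$ut * d2^2 - s2$ut * d1^2) / (d1 * d2 * (d2 - d1))
      tau <- mu * a
      # drop samples whose outer stencil leaves the fluid
      ci <- pmin(pmax(ceiling((s2$P[, 1] - grid$origin[1]) / h), 1), grid$nx)
      cj <- pmin(pmax(ceiling((s2$P[, 2] - grid$origin[2]) / h), 1), grid$ny)
      ok <- state$cell_fluid[cbind(ci, cj)]
      tau[!ok] <- 0
      out[[length(out) + 1L]] <- tibble(
        segment = si, side = if (side > 0) "A" else "B",
        s_mm = tt * len * MM_PER_M,
        tau_x = tau * tangent[1], tau_y = tau * tangent[2])
    }
  }
  dplyr::bind_rows(out)
}

#' Run the immersed-boundary solver over cardiac cycles
#'
#' Advances the flow through `n_cycles` cardiac cycles, recording gauge
#' pressures at the probes and wall shear samples on the device frame every
#' step, orifice fluxes, and full field snapshots at the configured stride.
#' Deterministic for fixed inputs.
#'
#' @param dense A `dense_motion` (carrying the embedded device, if any).
#' @param props [fluid_properties()].
#' @param config [solver_config()].
#' @param probes A [probe_set()], or `NULL` to skip probe recording.
#' @param n_cycles Number of cardiac cycles (>= 0).
#' @param wall_stride Steps between wall-shear samples (1 records every step).
#' @param verbose Print progress.
#' @return A `vimflow_run` object: `probe_series`, `wall_series`, `fluxes`
#'   tibbles, `snapshots`, the final `state`, and the systole window.
#' @export
run_cycles <- function(dense, props = fluid_properties(),
                       config = solver_config(), probes = NULL,
                       n_cycles = 2, wall_stride = 1L, verbose = FALSE) {
  stopifnot(inherits(dense, "dense_motion"))
  clear_solver_caches()
  on.exit(clear_solver_caches(), add = TRUE)
  domain <- lv_domain(dense, config)
  tc <- dense$cycle_duration
  n_steps_cycle <- as.integer(round(tc / config$dt))
  if (abs(n_steps_cycle * config$dt - tc) > 1e-9) {
    config$dt <- tc / n_steps_cycle
  }
  state <- new_flow_state(domain$grid)
  ctx0 <- build_context(domain, 0, config)
  state$cell_fluid <- ctx0$fluid
  mu <- props$dynamic_viscosity
  dev_m <- if (!is.null(dense$device)) {
    lapply(dense$device$segments, function(sg) sg / MM_PER_M)
  } else NULL

  n_total <- n_steps_cycle * n_cycles
  probe_rows <- vector("list", n_total)
  wall_rows <- vector("list", n_total)
  flux_rows <- vector("list", n_total)
  snapshots <- list()
  if (n_total > 0) {
    for (k in seq_len(n_total)) {
      t_new <- k * config$dt
      ctx <- build_context(domain, t_new %% tc, config)
      state <- step_flow(state, ctx, props, config)
      state$time <- t_new   # keep exact accumulated time
      dg <- attr(state, "diagnostics")
      flux_rows[[k]] <- tibble(time = t_new, mitral_flux = dg$mitral_flux,
                               aortic_flux = dg$aortic_flux,
                               div_max = dg$div_max, cfl = dg$cfl)
      if (!is.null(probes)) {
        pr <- sample_probe_pressure(state, probes)
        pr$time <- t_new
        probe_rows[[k]] <- pr
      }
      if (!is.null(dev_m) && (k %% wall_stride == 0L)) {
        ws <- device_wall_shear(state, dev_m, mu)
        ws$time <- t_new
        wall_rows[[k]] <- ws
      }
      if (k %% config$snapshot_stride == 0L) {
        snapshots[[length(snapshots) + 1L]] <- state
      }
      if (verbose && k %% 200 == 0) {
        inform(sprintf("step %d/%d (t = %.3f s, div %.2e)", k, n_total,
                       t_new, dg$div_max))
      }
    }
  }
  sw <- systole_window_of(dense)
  structure(list(
    probe_series = dplyr::bind_rows(probe_rows),
    wall_series = dplyr::bind_rows(wall_rows),
    fluxes = dplyr::bind_rows(flux_rows),
    snapshots = snapshots, state = state,
    systole_window = sw, cycle_duration = tc,
    n_cycles = n_cycles, config = config, props = props,
    probes = probes, dense = dense
  ), class = "vimflow_run")
}

#' Systolic (ejection) window of a dense motion trajectory
#'
#' The contiguous interval around peak ejection where the cavity-area rate is
#' below a small fraction of its peak shrinking rate. The window may wrap the
#' cycle start, in which case its lower bound is negative; wrap times with
#' `((t - window[1]) %% cycle) + window[1]` before comparing.
#'
#' @param dense A `dense_motion`.
#' @param rel_threshold Fraction of the peak |dA/dt| treated as "shrinking".
#' @return Length-2 numeric window (s).
#' @export
systole_window_of <- function(dense, rel_threshold = 0.02) {
  tc <- dense$cycle_duration
  n <- 2000L
  tt <- (seq_len(n) - 1L) * tc / n
  da <- dense$dareadt_fun(tt)
  thr <- rel_threshold * max(-da)
  ip <- which.min(da)
  lo <- ip; cnt <- 0L
  while (cnt < n && da[((lo - 2L) %% n) + 1L] < -thr) {
    lo <- ((lo - 2L) %% n) + 1L; cnt <- cnt + 1L
  }
  hi <- ip; cnt <- 0L
  while (cnt < n && da[(hi %% n) + 1L] < -thr) {
    hi <- (hi %% n) + 1L; cnt <- cnt + 1L
  }
  t0 <- tt[lo]; t1 <- tt[hi]
  if (t1 < t0) t0 <- t0 - tc
  c(t0, t1)
}

#' @export
print.vimflow_run <- function(x, ...) {
  cat(sprintf("<vimflow_run> %d cycles of %.3g s at dt = %.3g s\n",
              x$n_cycles, x$cycle_duration, x$config$dt))
  if (nrow(x$fluxes) > 0) {
    cat(sprintf("  max |div u| %.2e 1/s, max CFL %.2f\n",
                max(x$fluxes$div_max), max(x$fluxes$cfl)))
  }
  invisible(x)
}

#' @rdname run_cycles
#' @param x A `vimflow_run`.
#' @param ... Unused.
#' @export
tidy.vimflow_run <- function(x, ...) {
  x$probe_series
}

#' @rdname run_cycles
#' @export
glance.vimflow_run <- function(x, ...) {
  tibble(n_cycles = x$n_cycles, dt = x$config$dt,
         n_steps = nrow(x$fluxes),
         max_div = if (nrow(x$fluxes)) max(x$fluxes$div_max) else NA_real_,
         max_cfl = if (nrow(x$fluxes)) max(x$fluxes$cfl) else NA_real_,
         systole_start = x$systole_window[1],
         systole_end = x$systole_window[2])
}

#' Run a static domain to steady state
#'
#' Steps a channel (or other static) domain until the velocity field stops
#' changing; used for analytic verification cases.
#'
#' @param domain A `flow_domain` with time-independent geometry.
#' @param props [fluid_properties()].
#' @param config [solver_config()].
#' @param max_steps Step budget.
#' @param tol Steady-state tolerance on the max velocity update per step
#'   (m/s).
#' @return The final `flow_state` (diagnostics attribute from the last step).
#' @export
run_steady <- function(domain, props = fluid_properties(),
                       config = solver_config(), max_steps = 4000,
                       tol = 1e-7) {
  clear_solver_caches()
  on.exit(clear_solver_caches(), add = TRUE)
  state <- new_flow_state(domain$grid)
  ctx <- build_context(domain, 0, config)
  state$cell_fluid <- ctx$fluid
  for (k in seq_len(max_steps)) {
    uold <- state$u
    state <- step_flow(state, ctx, props, config)
    if (max(abs(state$u - uold)) < tol) break
  }
  state
}

# ---------------------------------------------------------------------------
# doubly periodic step (Galilean-invariance sanity path); fields stored as
# nx x ny matrices of face velocities with implicit wrap-around
# ---------------------------------------------------------------------------

#' Advance a doubly periodic box by one step
#'
#' Semi-Lagrangian advection, explicit viscosity and an FFT pressure
#' projection on a wall-free periodic box. Used for invariance checks (adding
#' a uniform velocity shifts the solution by exactly that velocity).
#'
#' @param u,v nx x ny face-velocity matrices (periodic).
#' @param grid From `periodic_domain()$grid` (square, nx == ny).
#' @param props [fluid_properties()].
#' @param dt Time step (s).
#' @return List with updated `u`, `v`.
#' @export
step_periodic <- function(u, v, grid, props, dt) {
  n <- grid$nx; h <- grid$h
  nu <- props$dynamic_viscosity / props$density
  wrap <- function(M, di, dj) {
    M[((seq_len(n) - 1 + di) %% n) + 1, ((seq_len(n) - 1 + dj) %% n) + 1]
  }
  # semi-Lagrangian backtrace with periodic bilinear sampling
  samp <- function(F0, gx, gy) {
    i0 <- floor(gx); j0 <- floor(gy)
    fx <- gx - i0; fy <- gy - j0
    w <- function(k) ((k - 1) %% n) + 1
    F0[cbind(c(w(i0)), c(w(j0)))] * (1 - fx) * (1 - fy) +
      F0[cbind(c(w(i0 + 1)), c(w(j0)))] * fx * (1 - fy) +
      F0[cbind(c(w(i0)), c(w(j0 + 1)))] * (1 - fx) * fy +
      F0[cbind(c(w(i0 + 1)), c(w(j0 + 1)))] * fx * fy
  }
  I <- matrix(rep(seq_len(n), n), n, n)
  J <- t(I)
  # u faces at (i-1, j-1/2); v at (i-1/2, j-1) in grid units
  vbar_u <- 0.25 * (v + wrap(v, -1, 0) + wrap(v, 0, 1) + wrap(v, -1, 1))
  ubar_v <- 0.25 * (u + wrap(u, 0, -1) + wrap(u, 1, 0) + wrap(u, 1, -1))
  gx_u <- (I - 1) - u * dt / h; gy_u <- (J - 0.5) - vbar_u * dt / h
  gx_v <- (I - 0.5) - ubar_v * dt / h; gy_v <- (J - 1) - v * dt / h
  ua <- samp(u, gx_u + 1, gy_u + 0.5)
  va <- samp(v, gx_v + 0.5, gy_v + 1)
  lap <- function(M) (wrap(M, 1, 0) + wrap(M, -1, 0) + wrap(M, 0, 1) +
                        wrap(M, 0, -1) - 4 * M) / h^2
  us <- ua + dt * nu * lap(u)
  vs <- va + dt * nu * lap(v)
  # FFT projection
  div <- (wrap(us, 1, 0) - us) / h + (wrap(vs, 0, 1) - vs) / h
  dhat <- stats::fft(div)
  kx <- 2 * pi * (seq_len(n) - 1) / n
  lam <- outer(2 * cos(kx) - 2, 2 * cos(kx) - 2, "+") / h^2
  lam[1, 1] <- 1
  phat <- dhat / lam
  phat[1, 1] <- 0
  phi <- Re(stats::fft(phat, inverse = TRUE)) / n^2
  us <- us - (phi - wrap(phi, -1, 0)) / h
  vs <- vs - (phi - wrap(phi, 0, -1)) / h
  list(u = us, v = vs)
}
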