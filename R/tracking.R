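# Wall-motion recovery: cubic B-spline free-form deformation (FFD)
# registration between cardiac phases, boundary propagation through the
# cycle, Hausdorff validation and dense temporal interpolation.

#' Registration configuration for FFD wall tracking
#'
#' @param control_spacing Control-point spacing of the finest level (mm).
#' @param regularization_weight Bending-energy weight (dimensionless, >= 0).
#' @param max_iterations Gradient-descent iterations per level.
#' @param convergence_tolerance Stop when the largest control-point update of
#'   an iteration falls below this (mm).
#' @param multiresolution_levels Coarse-to-fine levels (>= 1); level k uses
#'   spacing `control_spacing * 2^(levels - k)`.
#' @return A `tracking_config` object.
#' @export
tracking_config <- function(control_spacing = 8,
                            regularization_weight = 0.01,
                            max_iterations = 120,
                            convergence_tolerance = 1e-3,
                            multiresolution_levels = 2) {
  stopifnot(control_spacing > 0, regularization_weight >= 0,
            max_iterations >= 1, convergence_tolerance > 0,
            multiresolution_levels >= 1)
  structure(list(control_spacing = control_spacing,
                 regularization_weight = regularization_weight,
                 max_iterations = as.integer(max_iterations),
                 convergence_tolerance = convergence_tolerance,
                 multiresolution_levels = as.integer(multiresolution_levels)),
            class = "tracking_config")
}

# cubic uniform B-spline basis values for local coordinate t in [0,1):
# weights of control points i-1, i, i+1, i+2
bspline_w <- function(t) {
  cbind((1 - t)^3 / 6,
        (3 * t^3 - 6 * t^2 + 4) / 6,
        (-3 * t^3 + 3 * t^2 + 3 * t + 1) / 6,
        t^3 / 6)
}

#' Free-form deformation displacement field
#'
#' A dense displacement interpolated from a regular grid of control-point
#' displacements by cubic uniform B-splines (C2 inside the grid).
#'
#' @param origin 2D position of control node (1,1) (mm).
#' @param spacing Control spacing (mm).
#' @param dx,dy Matrices of control displacements (mm), dim `gx x gy`.
#' @return A `displacement_field` object.
#' @export
displacement_field <- function(origin, spacing, dx, dy) {
  stopifnot(spacing > 0, all(dim(dx) == dim(dy)))
  structure(list(origin = as.numeric(origin), spacing = spacing,
                 dx = dx, dy = dy), class = "displacement_field")
}

# sparse-ish weight structure mapping control displacements to displacements
# at fixed evaluation points; returns list(idx = n x 16 linear indices into
# the control grid, w = n x 16 weights)
ffd_weights <- function(field_geom, pts) {
  gx <- field_geom$gx; gy <- field_geom$gy
  u <- (pts[, 1] - field_geom$origin[1]) / field_geom$spacing
  v <- (pts[, 2] - field_geom$origin[2]) / field_geom$spacing
  iu <- floor(u); iv <- floor(v)
  if (any(iu < 1 | iu > gx - 3 | iv < 1 | iv > gy - 3)) {
    abort("points fall outside the displacement field's control grid")
  }
  tu <- u - iu; tv <- v - iv
  wu <- bspline_w(tu); wv <- bspline_w(tv)
  n <- nrow(pts)
  idx <- matrix(0L, n, 16)
  w <- matrix(0, n, 16)
  for (a in 1:4) {
    for (b in 1:4) {
      k <- (a - 1) * 4 + b
      idx[, k] <- (iu + a - 2L) + (iv + b - 2L - 1L) * gx + 0L
      # control grid stored column-major: linear index = row + (col-1)*gx
      idx[, k] <- (iu + a - 1L) + (iv + b - 2L) * gx
      w[, k] <- wu[, a] * wv[, b]
    }
  }
  list(idx = idx, w = w)
}

#' Evaluate a displacement field
#'
#' @param field A `displacement_field`.
#' @param pts n x 2 matrix of positions (mm); must lie inside the valid
#'   region of the control grid.
#' @return n x 2 matrix of displacements (mm).
#' @export
eval_displacement <- function(field, pts) {
  pts <- matrix(as.numeric(pts), ncol = 2)
  geom <- list(origin = field$origin, spacing = field$spacing,
               gx = nrow(field$dx), gy = ncol(field$dx))
  ww <- ffd_weights(geom, pts)
  dx <- rowSums(ww$w * matrix(field$dx[ww$idx], nrow(pts), 16))
  dy <- rowSums(ww$w * matrix(field$dy[ww$idx], nrow(pts), 16))
  cbind(dx, dy)
}

#' Apply a displacement field to points
#'
#' @inheritParams eval_displacement
#' @return Displaced points, n x 2.
#' @export
apply_displacement <- function(field, pts) {
  pts + eval_displacement(field, pts)
}

# control grid covering pts with the margin cubic B-splines need
make_field_geom <- function(pts_list, spacing, margin = 2) {
  allp <- do.call(rbind, pts_list)
  xr <- range(allp[, 1]); yr <- range(allp[, 2])
  origin <- c(xr[1] - (margin + 0.5) * spacing, yr[1] - (margin + 0.5) * spacing)
  gx <- ceiling((xr[2] - origin[1]) / spacing) + margin + 2
  gy <- ceiling((yr[2] - origin[2]) / spacing) + margin + 2
  list(origin = origin, spacing = spacing, gx = as.integer(gx), gy = as.integer(gy))
}

# symmetric mean squared closest-point distance and its gradient with respect
# to the deformed source points (correspondences frozen at the current pose)
symmetric_msd <- function(def, tgt, with_grad = FALSE) {
  n <- nrow(def); m <- nrow(tgt)
  d2 <- outer(rowSums(def^2), rowSums(tgt^2), "+") - 2 * def %*% t(tgt)
  d2[d2 < 0] <- 0
  j_of_i <- max.col(-d2, ties.method = "first")   # nearest target per source
  i_of_j <- max.col(-t(d2), ties.method = "first") # nearest source per target
  e1 <- mean(d2[cbind(seq_len(n), j_of_i)])
  e2 <- mean(d2[cbind(i_of_j, seq_len(m))])
  val <- 0.5 * (e1 + e2)
  if (!with_grad) return(list(value = val))
  g <- 2 * (def - tgt[j_of_i, , drop = FALSE]) / n * 0.5
  resid <- def[i_of_j, , drop = FALSE] - tgt
  for (j in seq_len(m)) {
    g[i_of_j[j], ] <- g[i_of_j[j], ] + 2 * resid[j, ] / m * 0.5
  }
  list(value = val, grad = g)
}

# discrete bending energy of the control grid (sum of squared second
# differences along x, y and mixed), value + gradient
bending_energy <- function(dx, dy) {
  val <- 0
  gdx <- matrix(0, nrow(dx), ncol(dx)); gdy <- gdx
  second_diff <- function(m) {
    dxx <- m[-c(1, 2), ] - 2 * m[-c(1, nrow(m)), ] + m[-c(nrow(m) - 1, nrow(m)), ]
    dyy <- m[, -c(1, 2)] - 2 * m[, -c(1, ncol(m))] + m[, -c(ncol(m) - 1, ncol(m))]
    dxy <- diff(t(diff(m)))  # (nx-1) x (ny-1) mixed differences, transposed
    list(dxx = dxx, dyy = dyy, dxy = t(dxy))
  }
  accum <- function(m) {
    sd <- second_diff(m)
    v <- sum(sd$dxx^2) + sum(sd$dyy^2) + 2 * sum(sd$dxy^2)
    g <- matrix(0, nrow(m), ncol(m))
    nr <- nrow(m); nc <- ncol(m)
    # adjoint of the xx operator
    t1 <- 2 * sd$dxx
    g[-c(1, 2), ] <- g[-c(1, 2), ] + t1
    g[-c(1, nr), ] <- g[-c(1, nr), ] - 2 * t1
    g[-c(nr - 1, nr), ] <- g[-c(nr - 1, nr), ] + t1
    t2 <- 2 * sd$dyy
    g[, -c(1, 2)] <- g[, -c(1, 2)] + t2
    g[, -c(1, nc)] <- g[, -c(1, nc)] - 2 * t2
    g[, -c(nc - 1, nc)] <- g[, -c(nc - 1, nc)] + t2
    t3 <- 4 * sd$dxy           # 2 * weight 2
    g[-1, -1] <- g[-1, -1] + t3
    g[-nr, -1] <- g[-nr, -1] - t3
    g[-1, -nc] <- g[-1, -nc] - t3
    g[-nr, -nc] <- g[-nr, -nc] + t3
    list(v = v, g = g)
  }
  ax <- accum(dx); ay <- accum(dy)
  ncp <- length(dx)
  list(value = (ax$v + ay$v) / ncp, gdx = ax$g / ncp, gdy = ay$g / ncp)
}

as_boundary_points <- function(x) {
  if (inherits(x, "mask_stack")) abort("pass one mask's contour, not a stack")
  if (is.list(x) && !is.null(x$masks)) abort("pass point matrices or a single mask")
  if (is.matrix(x) && ncol(x) == 2) return(x)
  abort("boundaries must be n x 2 point matrices (use mask_contour() for masks)")
}

#' Register two boundaries by free-form deformation
#'
#' Recovers a smooth displacement field carrying `source` onto `target` by
#' minimizing the symmetric mean squared closest-point distance between the
#' deformed source and the target boundary, with a bending-energy penalty on
#' the control grid. Gradient descent with backtracking line search,
#' coarse-to-fine over the configured multiresolution levels; the objective is
#' non-increasing by construction.
#'
#' @param source,target n x 2 boundary point matrices sharing a coordinate
#'   frame (mm). For raster masks, extract contours with [mask_contour()].
#' @param config A [tracking_config()].
#' @return An `ffd_registration`: the fitted `field`, per-iteration
#'   `objective` trace, `converged` flag and the final objective value.
#' @export
ffd_register <- function(source, target, config = tracking_config()) {
  src <- as_boundary_points(source)
  tgt <- as_boundary_points(target)
  bb_s <- apply(src, 2, range); bb_t <- apply(tgt, 2, range)
  if (bb_s[2, 1] < bb_t[1, 1] || bb_s[1, 1] > bb_t[2, 1] ||
      bb_s[2, 2] < bb_t[1, 2] || bb_s[1, 2] > bb_t[2, 2]) {
    abort("source and target extents do not overlap")
  }
  lam <- config$regularization_weight
  trace_levels <- list()
  field <- NULL
  converged <- FALSE
  for (lev in seq_len(config$multiresolution_levels)) {
    spacing <- config$control_spacing *
      2^(config$multiresolution_levels - lev)
    geom <- make_field_geom(list(src, tgt), spacing)
    # initialize from the previous (coarser) level
    dx <- matrix(0, geom$gx, geom$gy); dy <- dx
    if (!is.null(field)) {
      cx <- geom$origin[1] + (seq_len(geom$gx) - 1) * geom$spacing
      cy <- geom$origin[2] + (seq_len(geom$gy) - 1) * geom$spacing
      nodes <- cbind(rep(cx, times = geom$gy), rep(cy, each = geom$gx))
      ok <- tryCatch({
        d <- eval_displacement(field, nodes)
        dx[] <- d[, 1]; dy[] <- d[, 2]
        TRUE
      }, error = function(e) FALSE)
      if (!ok) { dx[] <- 0; dy[] <- 0 }
    }
    ww <- ffd_weights(geom, src)
    n16 <- ncol(ww$w)
    eval_obj <- function(dx, dy, with_grad = FALSE) {
      ddx <- rowSums(ww$w * matrix(dx[ww$idx], nrow(src), n16))
      ddy <- rowSums(ww$w * matrix(dy[ww$idx], nrow(src), n16))
      def <- src + cbind(ddx, ddy)
      ms <- symmetric_msd(def, tgt, with_grad)
      be <- bending_energy(dx, dy)
      out <- list(value = ms$value + lam * be$value)
      if (with_grad) {
        # chain rule through the fixed B-spline weights: scatter-add the
        # per-point gradients into the control grid
        gdx <- matrix(0, geom$gx, geom$gy); gdy <- gdx
        idx_vec <- as.vector(ww$idx)
        gdx_vec <- rep(0, length(gdx)); gdy_vec <- gdx_vec
        contrib_x <- as.vector(ms$grad[, 1] * ww$w)
        contrib_y <- as.vector(ms$grad[, 2] * ww$w)
        agg_x <- rowsum(contrib_x, idx_vec)
        agg_y <- rowsum(contrib_y, idx_vec)
        at <- as.integer(rownames(agg_x))
        gdx_vec[at] <- agg_x[, 1]; gdy_vec[at] <- agg_y[, 1]
        gdx[] <- gdx_vec; gdy[] <- gdy_vec
        out$gdx <- gdx + lam * be$gdx
        out$gdy <- gdy + lam * be$gdy
      }
      out
    }
    step0 <- spacing
    trace <- numeric(0)
    for (it in seq_len(config$max_iterations)) {
      ob <- eval_obj(dx, dy, with_grad = TRUE)
      trace <- c(trace, ob$value)
      gnorm2 <- sum(ob$gdx^2) + sum(ob$gdy^2)
      if (gnorm2 < 1e-20) { converged <- TRUE; break }
      alpha <- step0 / sqrt(gnorm2)
      improved <- FALSE
      for (bt in 1:25) {
        ndx <- dx - alpha * ob$gdx
        ndy <- dy - alpha * ob$gdy
        nv <- eval_obj(ndx, ndy)$value
        if (nv < ob$value - 1e-12) { improved <- TRUE; break }
        alpha <- alpha / 2
      }
      if (!improved) { converged <- TRUE; break }
      upd <- alpha * max(max(abs(ob$gdx)), max(abs(ob$gdy)))
      dx <- ndx; dy <- ndy
      if (upd < config$convergence_tolerance) { converged <- TRUE; break }
    }
    trace_levels[[lev]] <- trace
    field <- displacement_field(geom$origin, geom$spacing, dx, dy)
  }
  if (!converged) {
    warn("FFD registration did not converge within `max_iterations`; returning best-so-far field")
  }
  trace_all <- unlist(trace_levels)
  structure(list(field = field, objective = trace_all,
                 objective_by_level = trace_levels, converged = converged,
                 value = tail(trace_all, 1), config = config),
            class = "ffd_registration")
}

#' @export
print.ffd_registration <- function(x, ...) {
  cat(sprintf("<ffd_registration> %d iterations, objective %.4g, converged: %s\n",
              length(x$objective), x$value, x$converged))
  invisible(x)
}

#' @rdname ffd_register
#' @param x An `ffd_registration`.
#' @param ... Unused.
#' @export
tidy.ffd_registration <- function(x, ...) {
  f <- x$field
  gx <- nrow(f$dx); gy <- ncol(f$dx)
  tibble(node_x = rep(seq_len(gx), times = gy),
         node_y = rep(seq_len(gy), each = gx),
         x = f$origin[1] + (rep(seq_len(gx), times = gy) - 1) * f$spacing,
         y = f$origin[2] + (rep(seq_len(gy), each = gx) - 1) * f$spacing,
         dx = as.vector(f$dx), dy = as.vector(f$dy))
}

#' @rdname ffd_register
#' @export
glance.ffd_registration <- function(x, ...) {
  tibble(iterations = length(x$objective), objective = x$value,
         converged = x$converged,
         control_spacing = x$field$spacing)
}

#' Symmetric Hausdorff distance between two point sets
#'
#' `max(max_a min_b |a-b|, max_b min_a |a-b|)`.
#'
#' @param A,B Non-empty n x 2 (or n x k) point matrices.
#' @return Distance in the points' units.
#' @export
hausdorff_distance <- function(A, B) {
  A <- as.matrix(A); B <- as.matrix(B)
  if (nrow(A) == 0 || nrow(B) == 0) abort("point sets must be non-empty")
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
  d2[d2 < 0] <- 0
  max(max(apply(d2, 1, min)), max(apply(d2, 2, min)))^0.5
}

#' Propagate an initial boundary through a list of displacement fields
#'
#' Frame `k + 1` is the initial boundary composed with fields `1..k`; point
#' count and ordering are preserved.
#'
#' @param initial n x 2 boundary at the first frame (mm).
#' @param fields List of `displacement_field`s, one per subsequent frame.
#' @param times Frame times (length `length(fields) + 1`, s).
#' @param cycle_duration Cycle length (s); defaults to the time span.
#' @param mitral_idx,aortic_idx Optional orifice index ranges carried over.
#' @return A `motion_series`.
#' @export
propagate_boundary <- function(initial, fields, times = NULL,
                               cycle_duration = NULL,
                               mitral_idx = integer(0), aortic_idx = integer(0)) {
  nfr <- length(fields) + 1L
  times <- times %||% seq(0, 1, length.out = nfr)
  cycle_duration <- cycle_duration %||% (max(times) - min(times))
  n <- nrow(initial)
  xs <- matrix(0, n, nfr); ys <- matrix(0, n, nfr)
  xs[, 1] <- initial[, 1]; ys[, 1] <- initial[, 2]
  cur <- initial
  for (k in seq_along(fields)) {
    cur <- tryCatch(apply_displacement(fields[[k]], cur), error = function(e) {
      abort(sprintf("displacement field evaluation out of bounds at frame %d", k + 1L))
    })
    xs[, k + 1L] <- cur[, 1]; ys[, k + 1L] <- cur[, 2]
  }
  areas <- vapply(seq_len(nfr), function(k) polygon_area(cbind(xs[, k], ys[, k])),
                  numeric(1))
  structure(list(xs = xs, ys = ys, times = times, areas = areas,
                 mitral_idx = mitral_idx, aortic_idx = aortic_idx,
                 cycle_duration = cycle_duration, params = NULL,
                 aux = NULL, device = NULL),
            class = "motion_series")
}

#' Track a motion series frame-to-frame
#'
#' Registers consecutive frames of a series (frame k to frame k+1) and
#' reports the propagated boundaries and their Hausdorff distances to the
#' originals.
#'
#' @param series A `motion_series` (e.g. ground truth or mask contours).
#' @param config A [tracking_config()].
#' @return List with `fields`, `propagated` (a `motion_series`) and `report`
#'   (tibble: frame, hausdorff_mm).
#' @export
track_series <- function(series, config = tracking_config()) {
  nfr <- length(series$times)
  fields <- vector("list", nfr - 1L)
  for (k in seq_len(nfr - 1L)) {
    fields[[k]] <- ffd_register(frame_boundary(series, k),
                                frame_boundary(series, k + 1L), config)$field
  }
  prop <- propagate_boundary(frame_boundary(series, 1L), fields,
                             times = series$times,
                             cycle_duration = series$cycle_duration,
                             mitral_idx = series$mitral_idx,
                             aortic_idx = series$aortic_idx)
  hd <- vapply(seq_len(nfr), function(k) {
    hausdorff_distance(frame_boundary(prop, k), frame_boundary(series, k))
  }, numeric(1))
  list(fields = fields, propagated = prop,
       report = tibble(frame = seq_len(nfr), hausdorff_mm = hd))
}

#' Densify a motion series in time
#'
#' Periodic cubic-spline interpolation per boundary vertex, evaluated on a
#' uniform grid of `dt` steps over one cycle (the CT-derived motion is
#' interpolated to sub-millisecond resolution before driving the flow solve).
#' The interpolant passes through every input frame exactly.
#'
#' @param series A periodic `motion_series` (last frame equals the first).
#' @param dt Time step (s), must be positive and below the frame spacing.
#' @return A `dense_motion` object: vertex trajectories `xs`, `ys`
#'   (`n_points x n_steps`), `times`, area curve, a periodic `area_fun(t)`
#'   and derivative `dareadt_fun(t)` (mm^2/s), and the source series.
#' @export
interpolate_motion <- function(series, dt = 5e-4) {
  if (!is.finite(dt) || dt <= 0) abort("`dt` must be > 0")
  tc <- series$cycle_duration
  frame_dt <- diff(series$times)
  if (dt >= min(frame_dt)) abort("`dt` must be smaller than the frame spacing")
  per <- max(abs(frame_boundary(series, 1L) -
                 frame_boundary(series, length(series$times))))
  if (per > 1e-9) abort("series is not periodic (last frame != first)")
  n_steps <- max(2L, as.integer(round(tc / dt)))
  dt_eff <- tc / n_steps
  tt <- (seq_len(n_steps) - 1L) * dt_eff
  n <- nrow(series$xs)
  xs <- matrix(0, n, n_steps); ys <- xs
  vxs <- matrix(0, n, n_steps); vys <- vxs
  fx <- vector("list", n); fy <- vector("list", n)
  for (i in seq_len(n)) {
    fx[[i]] <- splinefun(series$times, series$xs[i, ], method = "periodic")
    fy[[i]] <- splinefun(series$times, series$ys[i, ], method = "periodic")
    xs[i, ] <- fx[[i]](tt)
    ys[i, ] <- fy[[i]](tt)
    vxs[i, ] <- fx[[i]](tt, deriv = 1)
    vys[i, ] <- fy[[i]](tt, deriv = 1)
  }
  areas <- vapply(seq_len(n_steps), function(k) polygon_area(cbind(xs[, k], ys[, k])),
                  numeric(1))
  afun <- splinefun(c(tt, tc), c(areas, areas[1]), method = "periodic")
  structure(list(
    xs = xs, ys = ys, vxs = vxs, vys = vys,
    times = tt, dt = dt_eff, cycle_duration = tc,
    areas = areas,
    area_fun = function(t) afun(t %% tc),
    dareadt_fun = function(t) afun(t %% tc, deriv = 1),
    vx_funs = fx, vy_funs = fy,
    mitral_idx = series$mitral_idx, aortic_idx = series$aortic_idx,
    device = series$device, series = series
  ), class = "dense_motion")
}

#' Boundary (and wall velocity) of a dense trajectory at an arbitrary time
#'
#' @param dense A `dense_motion`.
#' @param t Time (s); wrapped periodically into the cycle.
#' @param velocity Also return per-vertex wall velocities (mm/s).
#' @return n x 2 boundary matrix, or list(boundary, velocity).
#' @export
boundary_at <- function(dense, t, velocity = FALSE) {
  tc <- dense$cycle_duration
  tm <- t %% tc
  # bitwise pass-through at the source frame times
  if (!velocity && !is.null(dense$series)) {
    hit <- which(abs(dense$series$times - tm) < 1e-12)
    if (length(hit)) return(frame_boundary(dense$series, hit[1]))
  }
  # exact stored step if aligned with the dense grid
  k <- tm / dense$dt
  aligned <- abs(k - round(k)) < 1e-9
  if (aligned) {
    ki <- (as.integer(round(k)) %% ncol(dense$xs)) + 1L
    bnd <- cbind(dense$xs[, ki], dense$ys[, ki])
  } else {
    bnd <- cbind(vapply(dense$vx_funs, function(f) f(tm), numeric(1)),
                 vapply(dense$vy_funs, function(f) f(tm), numeric(1)))
  }
  if (!velocity) return(bnd)
  vel <- if (aligned) {
    ki <- (as.integer(round(k)) %% ncol(dense$xs)) + 1L
    cbind(dense$vxs[, ki], dense$vys[, ki])
  } else {
    cbind(vapply(dense$vx_funs, function(f) f(tm, deriv = 1), numeric(1)),
          vapply(dense$vy_funs, function(f) f(tm, deriv = 1), numeric(1)))
  }
  list(boundary = bnd, velocity = vel)
}
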