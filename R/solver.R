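# Incompressible Navier-Stokes on a fixed staggered (MAC) grid with the
# moving endocardial boundary and the rigid device frame imposed as immersed
# boundaries. Fractional-step (Chorin) projection: explicit advection
# (upwind or semi-Lagrangian) and viscous predictor, direct-forcing velocity
# imposition on boundary faces with sub-grid ghost interpolation of
# tangential neighbours, then a pressure projection solved with a sparse
# Cholesky factorization to machine-level divergence.
#
# All solver quantities are SI (m, s, Pa); geometry enters in mm and is
# converted at the domain builders.

#' Blood properties
#'
#' @param density Fluid density (kg/m^3).
#' @param dynamic_viscosity Dynamic viscosity (Pa s).
#' @return A `fluid_properties` object.
#' @export
fluid_properties <- function(density = 1060, dynamic_viscosity = 3e-3) {
  if (density <= 0 || dynamic_viscosity <= 0) {
    abort("density and viscosity must be positive")
  }
  structure(list(density = density, dynamic_viscosity = dynamic_viscosity),
            class = "fluid_properties")
}

#' Solver configuration
#'
#' @param dt Time step (s). The default matches the temporal resolution the
#'   wall motion is interpolated to.
#' @param cfl_max Largest admissible advective CFL number (0, 1].
#' @param div_tolerance Bound on the post-projection discrete divergence
#'   (1/s).
#' @param max_pressure_iterations Iterative-refinement passes allowed on the
#'   pressure solve.
#' @param advection `"upwind"` (donor-cell) or `"semilag"` (semi-Lagrangian,
#'   bilinear).
#' @param grid_h Grid spacing (m); when `NULL` the LV domain builder chooses
#'   it so at least `cells_across_lvot` cells span the outflow channel.
#' @param cells_across_lvot Minimum cells across the LVOT channel.
#' @param snapshot_stride Steps between stored field snapshots.
#' @param seed Integer seed recorded with runs (the solver itself is
#'   deterministic).
#' @return A `solver_config` object.
#' @export
solver_config <- function(dt = 5e-4, cfl_max = 0.9, div_tolerance = 1e-8,
                          max_pressure_iterations = 40,
                          advection = c("upwind", "semilag"),
                          grid_h = NULL, cells_across_lvot = 24,
                          snapshot_stride = 200L, seed = 1L) {
  advection <- match.arg(advection)
  if (dt <= 0) abort("`dt` must be positive")
  if (cfl_max <= 0 || cfl_max > 1) abort("`cfl_max` must lie in (0, 1]")
  structure(list(dt = dt, cfl_max = cfl_max, div_tolerance = div_tolerance,
                 max_pressure_iterations = as.integer(max_pressure_iterations),
                 advection = advection, grid_h = grid_h,
                 cells_across_lvot = cells_across_lvot,
                 snapshot_stride = as.integer(snapshot_stride),
                 seed = as.integer(seed)),
            class = "solver_config")
}

make_grid2d <- function(origin, h, nx, ny) {
  list(origin = as.numeric(origin), h = h, nx = as.integer(nx),
       ny = as.integer(ny),
       xc = origin[1] + (seq_len(nx) - 0.5) * h,
       yc = origin[2] + (seq_len(ny) - 0.5) * h,
       xf = origin[1] + (seq_len(nx + 1) - 1) * h,
       yf = origin[2] + (seq_len(ny + 1) - 1) * h)
}

new_flow_state <- function(grid, time = 0) {
  structure(list(
    u = matrix(0, grid$nx + 1, grid$ny),
    v = matrix(0, grid$nx, grid$ny + 1),
    p = matrix(0, grid$nx, grid$ny),
    age = matrix(0, grid$nx, grid$ny),
    cell_fluid = matrix(TRUE, grid$nx, grid$ny),
    time = time, grid = grid
  ), class = "flow_state")
}

# ---------------------------------------------------------------------------
# domains
# ---------------------------------------------------------------------------

#' Left-ventricle immersed-boundary domain
#'
#' Wraps a dense boundary trajectory (and optional embedded valve frame) as a
#' solver domain: cavity walls move with the interpolated motion, the frame is
#' a static internal obstacle, and the mitral/aortic orifices carry the flux
#' derived from the cavity-area rate (flow-direction gating: the aortic
#' orifice opens while the cavity shrinks, the mitral while it expands).
#'
#' @param dense A `dense_motion` (from [interpolate_motion()]); mm units.
#' @param config A [solver_config()].
#' @param margin Extra grid margin (cells).
#' @return A `flow_domain` object.
#' @export
lv_domain <- function(dense, config = solver_config(), margin = 3) {
  mm <- 1 / MM_PER_M
  h <- config$grid_h
  if (is.null(h)) {
    lw <- if (!is.null(dense$series$params)) dense$series$params$lvot_width else 18
    h <- (lw / config$cells_across_lvot) * mm
  }
  xr <- range(dense$xs) * mm; yr <- range(dense$ys) * mm
  origin <- c(xr[1] - margin * h, yr[1] - margin * h)
  nx <- ceiling((xr[2] - origin[1]) / h) + margin
  ny <- ceiling((yr[2] - origin[2]) / h) + margin
  grid <- make_grid2d(origin, h, nx, ny)
  obstacles <- NULL
  obstacle_cells <- NULL
  if (!is.null(dense$device)) {
    obstacles <- lapply(dense$device$segments, function(sg) sg * mm)
    # the frame is static: cells blocked by it never change
    centers <- cbind(rep(grid$xc, times = ny), rep(grid$yc, each = nx))
    near <- rep(FALSE, nrow(centers))
    for (sg in obstacles) {
      near <- near | (dist_points_to_segment(centers, sg[1, ], sg[2, ]) < 0.55 * h)
    }
    obstacle_cells <- matrix(near, nx, ny)
  }
  geometry_at <- function(t) {
    bv <- boundary_at(dense, t, velocity = TRUE)
    dadt <- dense$dareadt_fun(t) * mm^2          # m^2/s
    list(poly = bv$boundary * mm,
         vel = bv$velocity * mm,
         obstacles = obstacles,
         orifices = list(
           # outward-positive plug fluxes: the mitral orifice carries inflow
           # (negative outward) while the cavity expands, the aortic carries
           # outflow while it shrinks; the closed orifice reverts to a wall
           mitral = list(idx = dense$mitral_idx, flux = -max(dadt, 0)),
           aortic = list(idx = dense$aortic_idx, flux = max(-dadt, 0))
         ))
  }
  structure(list(type = "immersed", grid = grid, geometry_at = geometry_at,
                 obstacle_cells = obstacle_cells,
                 dense = dense, cycle_duration = dense$cycle_duration),
            class = "flow_domain")
}

#' Straight-channel verification domain
#'
#' A rectangular channel with immersed no-slip walls at arbitrary (grid
#' misaligned) heights and prescribed inlet/outlet velocity profiles; used
#' for analytic verification (plane Poiseuille, plug-flow age transport).
#'
#' @param length,width Channel dimensions (m).
#' @param h Grid spacing (m).
#' @param profile Function of the wall-normal coordinate `s` in \[0, width\]
#'   returning the streamwise inlet velocity (m/s).
#' @param wall_offset Distance of the lower wall above the grid origin (m);
#'   deliberately misaligning the walls with the grid exercises the sub-grid
#'   boundary treatment.
#' @return A `flow_domain`.
#' @export
channel_domain <- function(length, width, h, profile,
                           wall_offset = 0.37 * h) {
  pad <- 2 * h
  origin <- c(0, 0)
  nx <- ceiling(length / h)
  ny <- ceiling((width + wall_offset + pad) / h) + 2
  grid <- make_grid2d(origin, h, nx, ny)
  y0 <- wall_offset + h       # lower wall position
  y1 <- y0 + width            # upper wall position
  big <- length * 10
  # channel interior as a polygon: inlet (x=0) and outlet (x=length) are
  # orifice chords, the long sides are walls
  n_side <- max(8, ceiling(length / h))
  xs_side <- seq(0, length, length.out = n_side)
  # bottom wall left->right, outlet up, top wall right->left (CCW)
  poly <- rbind(cbind(xs_side, y0), cbind(rev(xs_side), y1))
  n_tot <- nrow(poly)
  outlet_idx <- c(n_side, n_side + 1L)              # (L,y0) -> (L,y1)
  inlet_idx <- c(n_tot, 1L)                         # (0,y1) -> (0,y0)
  geometry_at <- function(t) {
    list(poly = poly, vel = matrix(0, n_tot, 2), obstacles = NULL,
         orifices = list(
           inlet = list(idx = inlet_idx, profile = profile, sign = +1),
           outlet = list(idx = outlet_idx, profile = profile, sign = -1)
         ))
  }
  structure(list(type = "immersed", grid = grid, geometry_at = geometry_at,
                 channel = list(y0 = y0, y1 = y1, width = width, length = length),
                 cycle_duration = Inf),
            class = "flow_domain")
}

#' Doubly periodic test-box domain
#'
#' @param n Cells per side.
#' @param h Grid spacing (m).
#' @return A `flow_domain` with periodic boundary conditions and no walls.
#' @export
periodic_domain <- function(n, h) {
  grid <- make_grid2d(c(0, 0), h, n, n)
  structure(list(type = "periodic", grid = grid, cycle_duration = Inf),
            class = "flow_domain")
}

# ---------------------------------------------------------------------------
# step context: masks, face classification, prescribed values, ghosts,
# pressure factorization (cached on the fluid mask)
# ---------------------------------------------------------------------------

# crossing of short grid-aligned query segments with wall chains; returns for
# each query the crossing fraction in (0,1] (1 if none found); vectorized
# over all (query, edge) pairs at once
seg_crossing_frac <- function(px, py, qx, qy, chains) {
  n <- length(px)
  frac <- rep(1, n)
  if (n == 0) return(frac)
  rx <- qx - px; ry <- qy - py
  for (ch in chains) {
    m <- nrow(ch) - 1L
    ax <- ch[seq_len(m), 1]; ay <- ch[seq_len(m), 2]
    sx <- ch[seq_len(m) + 1L, 1] - ax; sy <- ch[seq_len(m) + 1L, 2] - ay
    # n x m arrays
    dax <- outer(-px, ax, "+")   # ax - px
    day <- outer(-py, ay, "+")
    den <- outer(rx, sy) - outer(ry, sx)
    tt <- (dax * rep(sy, each = n) - day * rep(sx, each = n)) / den
    uu <- (dax * ry - day * rx) / den
    hit <- is.finite(tt) & tt > 1e-12 & tt <= 1 &
      is.finite(uu) & uu >= -1e-12 & uu <= 1 + 1e-12
    tt[!hit] <- Inf
    tmin <- matrixStats_rowMins(tt)
    frac <- pmin(frac, pmin(tmin, 1))
  }
  frac
}

# factorizations are cached per fluid-mask so that the second cardiac cycle
# (identical geometry sequence) reuses the first cycle's factors; the cache
# is cleared at the start of every run and capped FIFO so long sessions with
# many runs stay within memory
poisson_cache <- local({
  store <- new.env(parent = emptyenv())
  fifo <- character(0)
  cap <- 1800L
  list(
    get = function(key) if (exists(key, store)) get(key, store) else NULL,
    set = function(key, val) {
      if (!exists(key, store)) {
        fifo <<- c(fifo, key)
        if (length(fifo) > cap) {
          drop <- fifo[1]
          fifo <<- fifo[-1]
          if (exists(drop, store)) rm(list = drop, envir = store)
        }
      }
      assign(key, val, store)
    },
    clear = function() {
      rm(list = ls(store), envir = store)
      fifo <<- character(0)
    }
  )
})

# fast row minima (base R, no loop over rows)
matrixStats_rowMins <- function(M) {
  out <- M[, 1]
  for (k in seq_len(ncol(M))[-1]) out <- pmin(out, M[, k])
  out
}

# compact hash key for a fluid mask; hits verify the mask exactly, so a
# collision only costs a rebuild
mask_key <- function(fluid) {
  w <- which(fluid)
  paste(nrow(fluid), ncol(fluid), length(w), sum(w),
        sum(w * seq_along(w)) %% 2147483647,
        sum(w %% 97), sep = "_")
}

build_poisson <- function(fluid, h) {
  nx <- nrow(fluid); ny <- ncol(fluid)
  id <- matrix(0L, nx, ny)
  cells <- which(fluid)
  id[cells] <- seq_along(cells)
  n <- length(cells)
  ij <- arrayInd(cells, c(nx, ny))
  ii <- ij[, 1]; jj <- ij[, 2]
  rows <- integer(0); cols <- integer(0); vals <- numeric(0)
  deg <- numeric(n)
  add_pair <- function(di, dj) {
    oi <- ii + di; oj <- jj + dj
    ok <- oi >= 1 & oi <= nx & oj >= 1 & oj <= ny
    ok[ok] <- fluid[cbind(oi[ok], oj[ok])]
    from <- id[cells[ok]]
    to <- id[cbind(oi[ok], oj[ok])]
    rows <<- c(rows, from); cols <<- c(cols, to)
    vals <<- c(vals, rep(-1, length(from)))
    deg[from] <<- deg[from] + 1
  }
  add_pair(1L, 0L); add_pair(-1L, 0L); add_pair(0L, 1L); add_pair(0L, -1L)
  A <- Matrix::sparseMatrix(i = c(rows, seq_len(n)), j = c(cols, seq_len(n)),
                            x = c(vals, deg), dims = c(n, n)) / h^2
  # pin the first fluid cell (Dirichlet p = 0): with a compatible right-hand
  # side the eliminated equation is satisfied automatically
  keep <- seq_len(n)[-1]
  Ar <- A[keep, keep, drop = FALSE]
  ch <- Matrix::Cholesky(Matrix::forceSymmetric(Ar), LDL = FALSE, perm = TRUE)
  list(A = A, chol = ch, id = id, cells = cells, keep = keep, n = n)
}

# ---------------------------------------------------------------------------
# The step context is split into a structural part (face classification,
# nearest-boundary mapping, ghost-crossing distances, Poisson factorization)
# cached per fluid mask -- the second cardiac cycle replays the first cycle's
# geometry bitwise, so these all hit the cache -- and a cheap per-step part
# (wall velocities, orifice plug values, inflow lists).
# ---------------------------------------------------------------------------

geometry_cache <- local({
  store <- new.env(parent = emptyenv())
  fifo <- character(0)
  cap <- 1800L
  list(
    get = function(key) if (exists(key, store)) get(key, store) else NULL,
    set = function(key, val) {
      if (!exists(key, store)) {
        fifo <<- c(fifo, key)
        if (length(fifo) > cap) {
          drop <- fifo[1]
          fifo <<- fifo[-1]
          if (exists(drop, store)) rm(list = drop, envir = store)
        }
      }
      assign(key, val, store)
    },
    clear = function() {
      rm(list = ls(store), envir = store)
      fifo <<- character(0)
    }
  )
})

clear_solver_caches <- function() {
  poisson_cache$clear()
  geometry_cache$clear()
}

ori_index_seq <- function(idx, n_poly) {
  if (length(idx) == 2 && idx[1] > idx[2]) c(idx[1]:n_poly, 1:idx[2])
  else if (length(idx) == 2) idx[1]:idx[2]
  else idx
}

# structural geometry for one fluid mask
build_geo <- function(grid, fluid, geom, domain) {
  nx <- grid$nx; ny <- grid$ny; h <- grid$h
  poly <- geom$poly
  fl <- fluid
  u_fluid <- matrix(FALSE, nx + 1, ny)
  u_fluid[2:nx, ] <- fl[1:(nx - 1), ] & fl[2:nx, ]
  v_fluid <- matrix(FALSE, nx, ny + 1)
  v_fluid[, 2:ny] <- fl[, 1:(ny - 1)] & fl[, 2:ny]

  # only non-fluid faces within two cells of the fluid are touched by the
  # stencils; deeper faces are zeroed ("dead")
  dil <- fl
  for (sh in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1),
                  c(1, 1), c(1, -1), c(-1, 1), c(-1, -1))) {
    dil <- dil | (shift_mat(fl + 0, sh[1], sh[2]) > 0)
  }
  dil2 <- dil
  for (sh in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
    dil2 <- dil2 | (shift_mat(dil + 0, sh[1], sh[2]) > 0)
  }
  u_band <- matrix(FALSE, nx + 1, ny)
  u_band[1:nx, ] <- dil2
  u_band[2:(nx + 1), ] <- u_band[2:(nx + 1), ] | dil2
  v_band <- matrix(FALSE, nx, ny + 1)
  v_band[, 1:ny] <- dil2
  v_band[, 2:(ny + 1)] <- v_band[, 2:(ny + 1)] | dil2
  u_presc_idx <- which(!u_fluid & u_band)
  v_presc_idx <- which(!v_fluid & v_band)
  u_dead_idx <- which(!u_fluid & !u_band)
  v_dead_idx <- which(!v_fluid & !v_band)

  u_pos <- cbind(rep(grid$xf, times = ny), rep(grid$yc, each = nx + 1))
  v_pos <- cbind(rep(grid$xc, times = ny + 1), rep(grid$yf, each = nx))
  closed_poly <- rbind(poly, poly[1, ])
  obst_chains <- geom$obstacles

  ori <- geom$orifices
  ori_of_vertex <- integer(nrow(poly))
  ori_static <- list()
  if (!is.null(ori)) {
    for (k in seq_along(ori)) {
      iseq <- ori_index_seq(ori[[k]]$idx, nrow(poly))
      ori_of_vertex[iseq] <- k
      chord <- poly[iseq, , drop = FALSE]
      a <- chord[1, ]; b <- chord[nrow(chord), ]
      tangent <- b - a; clen <- sqrt(sum(tangent^2))
      tangent <- tangent / clen
      nrm_out <- c(tangent[2], -tangent[1])  # outward for a CCW polygon
      ori_static[[k]] <- list(a = a, tangent = tangent, nrm_out = nrm_out,
                              clen = clen,
                              profile = ori[[k]]$profile,
                              sign = ori[[k]]$sign %||% 1)
    }
  }

  face_struct <- function(pos_idx, pos, comp) {
    m <- length(pos_idx)
    if (m == 0) {
      return(list(nearest = integer(0), dev_near = logical(0),
                  ori_id = integer(0), plug_comp = numeric(0),
                  profile_val = numeric(0)))
    }
    P <- pos[pos_idx, , drop = FALSE]
    dev_near <- rep(FALSE, m)
    if (!is.null(obst_chains)) {
      for (sg in obst_chains) {
        dev_near <- dev_near | (dist_points_to_segment(P, sg[1, ], sg[2, ]) < 0.75 * h)
      }
    }
    d2 <- outer(rowSums(P^2), rowSums(poly^2), "+") - 2 * P %*% t(poly)
    nearest <- max.col(-d2, ties.method = "first")
    oid <- ori_of_vertex[nearest]
    oid[dev_near] <- 0L
    plug_comp <- numeric(m)
    profile_val <- rep(NA_real_, m)
    for (k in seq_along(ori_static)) {
      sel <- which(oid == k)
      if (!length(sel)) next
      os <- ori_static[[k]]
      plug_comp[sel] <- os$nrm_out[comp]
      if (!is.null(os$profile)) {
        s_along <- abs((P[sel, 1] - os$a[1]) * os$tangent[1] +
                         (P[sel, 2] - os$a[2]) * os$tangent[2])
        profile_val[sel] <- os$sign * (-os$nrm_out[comp]) *
          vapply(s_along, os$profile, numeric(1))
      }
    }
    list(nearest = nearest, dev_near = dev_near, ori_id = oid,
         plug_comp = plug_comp, profile_val = profile_val)
  }
  uS <- face_struct(u_presc_idx, u_pos, 1L)
  vS <- face_struct(v_presc_idx, v_pos, 2L)

  chains <- c(list(closed_poly), if (is.null(obst_chains)) NULL else obst_chains)
  ghost_tbl <- function(face_fluid, pos, d_vec) {
    nfx <- nrow(face_fluid); nfy <- ncol(face_fluid)
    di <- d_vec[1]; dj <- d_vec[2]
    src <- which(face_fluid)
    ij <- arrayInd(src, c(nfx, nfy))
    oi <- ij[, 1] + di; oj <- ij[, 2] + dj
    inb <- oi >= 1 & oi <= nfx & oj >= 1 & oj <= nfy
    nb_fluid <- rep(FALSE, length(src))
    nb_fluid[inb] <- face_fluid[cbind(oi[inb], oj[inb])]
    need <- which(!nb_fluid)
    if (length(need) == 0) return(list(idx = integer(0)))
    fidx <- src[need]
    P <- pos[fidx, , drop = FALSE]
    frac <- seg_crossing_frac(P[, 1], P[, 2],
                              P[, 1] + di * h, P[, 2] + dj * h, chains)
    d <- pmax(frac * h, 0.1 * h)
    ci <- pmin(pmax(ij[need, 1] + di, 1), nfx)
    cj <- pmin(pmax(ij[need, 2] + dj, 1), nfy)
    list(idx = fidx, d = d, nb = (cj - 1L) * nfx + ci)
  }
  ghosts <- list(u_n = ghost_tbl(u_fluid, u_pos, c(0L, 1L)),
                 u_s = ghost_tbl(u_fluid, u_pos, c(0L, -1L)),
                 v_e = ghost_tbl(v_fluid, v_pos, c(1L, 0L)),
                 v_w = ghost_tbl(v_fluid, v_pos, c(-1L, 0L)))

  # orifice faces adjacent to exactly one fluid cell, with outward signs
  of_struct <- function(presc_idx, ori_id, horiz) {
    sel <- which(ori_id > 0)
    if (length(sel) == 0) return(NULL)
    idx <- presc_idx[sel]
    if (horiz) {
      ij <- arrayInd(idx, c(nx + 1, ny))
      iu <- ij[, 1]; j <- ij[, 2]
      lf <- rep(FALSE, length(idx)); rf <- lf
      ok <- iu > 1; lf[ok] <- fl[cbind(iu[ok] - 1L, j[ok])]
      ok <- iu <= nx; rf[ok] <- fl[cbind(iu[ok], j[ok])]
    } else {
      ij <- arrayInd(idx, c(nx, ny + 1))
      i <- ij[, 1]; jv <- ij[, 2]
      lf <- rep(FALSE, length(idx)); rf <- lf
      ok <- jv > 1; lf[ok] <- fl[cbind(i[ok], jv[ok] - 1L)]
      ok <- jv <= ny; rf[ok] <- fl[cbind(i[ok], jv[ok])]
    }
    keep <- xor(lf, rf)
    if (!any(keep)) return(NULL)
    data.frame(idx = idx[keep], sign = ifelse(lf[keep], +1, -1),
               ori = ori_id[sel][keep], presc_pos = sel[keep])
  }
  list(fluid = fluid,
       u_fluid = u_fluid, v_fluid = v_fluid,
       u_presc_idx = u_presc_idx, v_presc_idx = v_presc_idx,
       u_dead_idx = u_dead_idx, v_dead_idx = v_dead_idx,
       uS = uS, vS = vS, ori_static = ori_static, ghosts = ghosts,
       of_u = of_struct(u_presc_idx, uS$ori_id, TRUE),
       of_v = of_struct(v_presc_idx, vS$ori_id, FALSE))
}

# full step context: cached structure plus per-step wall/orifice values
build_context <- function(domain, t, config) {
  grid <- domain$grid
  nx <- grid$nx; ny <- grid$ny; h <- grid$h
  geom <- domain$geometry_at(t)
  poly <- geom$poly
  centers <- cbind(rep(grid$xc, times = ny), rep(grid$yc, each = nx))
  fluid <- matrix(points_in_polygon(centers, poly), nx, ny)
  if (!is.null(domain$obstacle_cells)) {
    fluid <- fluid & !domain$obstacle_cells
  } else if (!is.null(geom$obstacles)) {
    near <- rep(FALSE, nrow(centers))
    for (sg in geom$obstacles) {
      near <- near | (dist_points_to_segment(centers, sg[1, ], sg[2, ]) < 0.55 * h)
    }
    fluid <- fluid & !matrix(near, nx, ny)
  }

  key <- mask_key(fluid)
  geo <- geometry_cache$get(key)
  if (is.null(geo) || !identical(geo$fluid, fluid)) {
    geo <- build_geo(grid, fluid, geom, domain)
    geometry_cache$set(key, geo)
  }
  pois <- poisson_cache$get(key)
  if (is.null(pois) || !identical(pois$fluid, fluid)) {
    pois <- build_poisson(fluid, h)
    pois$fluid <- fluid
    poisson_cache$set(key, pois)
  }

  vel <- geom$vel
  ori <- geom$orifices
  open_k <- integer(0)
  q_k <- numeric(length(geo$ori_static))
  for (k in seq_along(geo$ori_static)) {
    os <- geo$ori_static[[k]]
    if (!is.null(os$profile)) {
      open_k <- c(open_k, k)
    } else {
      q_k[k] <- ori[[k]]$flux / os$clen
      if (abs(ori[[k]]$flux) > 0) open_k <- c(open_k, k)
    }
  }

  face_values <- function(S, presc_idx, comp) {
    val <- vel[cbind(S$nearest, rep(comp, length(S$nearest)))]
    val[S$dev_near] <- 0
    oflag <- integer(length(val))
    for (k in open_k) {
      sel <- which(S$ori_id == k)
      if (!length(sel)) next
      os <- geo$ori_static[[k]]
      val[sel] <- if (!is.null(os$profile)) S$profile_val[sel]
                  else q_k[k] * S$plug_comp[sel]
      oflag[sel] <- k
    }
    list(val = val, oflag = oflag)
  }
  uv <- face_values(geo$uS, geo$u_presc_idx, 1L)
  vv <- face_values(geo$vS, geo$v_presc_idx, 2L)
  u_presc <- matrix(0, nx + 1, ny); u_presc[geo$u_presc_idx] <- uv$val
  v_presc <- matrix(0, nx, ny + 1); v_presc[geo$v_presc_idx] <- vv$val

  ghosts <- geo$ghosts
  for (nm in c("u_n", "u_s")) {
    if (length(ghosts[[nm]]$idx)) ghosts[[nm]]$wall <- u_presc[ghosts[[nm]]$nb]
  }
  for (nm in c("v_e", "v_w")) {
    if (length(ghosts[[nm]]$idx)) ghosts[[nm]]$wall <- v_presc[ghosts[[nm]]$nb]
  }

  filt <- function(of) {
    if (is.null(of)) return(NULL)
    of <- of[of$ori %in% open_k, , drop = FALSE]
    if (nrow(of) == 0) NULL else of
  }
  ctx <- list(grid = grid, fluid = fluid,
              u_fluid = geo$u_fluid, v_fluid = geo$v_fluid,
              u_presc = u_presc, v_presc = v_presc,
              u_presc_idx = geo$u_presc_idx, v_presc_idx = geo$v_presc_idx,
              u_dead_idx = geo$u_dead_idx, v_dead_idx = geo$v_dead_idx,
              ghosts = ghosts, poisson = pois, geom = geom, time = t,
              periodic = FALSE,
              orifice_faces = list(u = filt(geo$of_u), v = filt(geo$of_v)))
  ctx$inflow_cells <- inflow_cell_list(ctx)
  ctx
}

# cells whose E/W/N/S neighbour lies across an inflowing orifice face (the
# age scalar enters at zero age there)
inflow_cell_list <- function(ctx) {
  nx <- ctx$grid$nx; ny <- ctx$grid$ny
  out <- list(E = integer(0), W = integer(0), N = integer(0), S = integer(0))
  fu <- ctx$orifice_faces$u
  if (!is.null(fu) && nrow(fu) > 0) {
    ij <- arrayInd(fu$idx, c(nx + 1, ny))
    vals <- ctx$u_presc[fu$idx]
    left <- fu$sign > 0     # fluid cell on the left of the face
    infl <- vals * fu$sign < 0
    cl <- (ij[, 2] - 1L) * nx + (ij[, 1] - 1L)   # left cell linear index
    cr <- (ij[, 2] - 1L) * nx + ij[, 1]
    out$E <- cl[left & infl]
    out$W <- cr[!left & infl]
  }
  fv <- ctx$orifice_faces$v
  if (!is.null(fv) && nrow(fv) > 0) {
    ij <- arrayInd(fv$idx, c(nx, ny + 1))
    vals <- ctx$v_presc[fv$idx]
    bot <- fv$sign > 0
    infl <- vals * fv$sign < 0
    cb <- (ij[, 2] - 2L) * nx + ij[, 1]
    ct <- (ij[, 2] - 1L) * nx + ij[, 1]
    out$N <- cb[bot & infl]
    out$S <- ct[!bot & infl]
  }
  out
}
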