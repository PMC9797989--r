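# One projection step of the immersed-boundary solver, the age-scalar
# transport, and the orifice flux derivation from the cavity-area rate.

shift_mat <- function(M, di, dj, fill = 0) {
  nr <- nrow(M); nc <- ncol(M)
  out <- matrix(fill, nr, nc)
  si <- max(1, 1 - di):min(nr, nr - di)
  sj <- max(1, 1 - dj):min(nc, nc - dj)
  out[si, sj] <- M[si + di, sj + dj]
  out
}

#' Orifice fluxes from the cavity-area rate
#'
#' The mass flow through each valve is derived from the rate of change of the
#' cavity area (the 2D analogue of deriving it from the change in mesh volume
#' per time step), gated by flow direction: while the cavity shrinks the
#' aortic orifice carries the outflow, while it expands the mitral orifice
#' carries the inflow.
#'
#' @param dense A `dense_motion`.
#' @param t Time (s); wrapped periodically into the cycle.
#' @return Tibble with `mitral_flux` and `aortic_flux` (m^2/s in this 2D
#'   setting; both non-negative, outward-positive at the aortic orifice and
#'   inward-positive at the mitral).
#' @export
flux_from_volume <- function(dense, t) {
  dadt <- dense$dareadt_fun(t) / MM_PER_M^2
  tibble(time = t,
         mitral_flux = pmax(dadt, 0),
         aortic_flux = pmax(-dadt, 0))
}

# ghost-corrected tangential neighbour values: linear interpolation between
# the face value and the wall velocity at its sub-grid crossing distance
apply_ghosts <- function(nbr, fld, g, h) {
  if (length(g$idx) == 0) return(nbr)
  uf <- fld[g$idx]
  nbr[g$idx] <- uf + (g$wall - uf) * (h / g$d)
  nbr
}

full_field <- function(fld, presc, presc_idx, dead_idx = NULL) {
  fld[presc_idx] <- presc[presc_idx]
  if (length(dead_idx)) fld[dead_idx] <- 0
  fld
}

divergence_of <- function(U, V, ctx) {
  nx <- ctx$grid$nx; ny <- ctx$grid$ny; h <- ctx$grid$h
  (U[2:(nx + 1), , drop = FALSE] - U[1:nx, , drop = FALSE]) / h +
    (V[, 2:(ny + 1), drop = FALSE] - V[, 1:ny, drop = FALSE]) / h
}

#' Advance the flow state by one time step
#'
#' Fractional-step projection: explicit advection and viscous predictor on
#' fluid faces, direct-forcing imposition of wall/orifice velocities on
#' boundary faces (with the orifice plug rescaled so the discrete boundary
#' flux balances exactly), pressure projection to the configured divergence
#' tolerance, and donor-cell transport of the age scalar with unit source.
#'
#' @param state A `flow_state`.
#' @param ctx Step context from the domain (internal; `run_cycles()` builds
#'   it). Carries the wall geometry, motion and orifice state at the new time
#'   level.
#' @param props [fluid_properties()].
#' @param config [solver_config()].
#' @return Updated `flow_state` with a `diagnostics` attribute (divergence,
#'   CFL, per-orifice fluxes, pressure residual history).
#' @export
step_flow <- function(state, ctx, props, config) {
  grid <- ctx$grid
  nx <- grid$nx; ny <- grid$ny; h <- grid$h
  dt <- config$dt
  rho <- props$density
  nu <- props$dynamic_viscosity / rho

  # CFL guard
  vmax <- max(max(abs(state$u)), max(abs(state$v)), 1e-12)
  cfl <- vmax * dt / h
  if (cfl > config$cfl_max) {
    abort(sprintf(
      "CFL %.2f exceeds cfl_max %.2f; reduce dt below %.3g s (or coarsen the grid)",
      cfl, config$cfl_max, config$cfl_max * h / vmax))
  }

  # fresh cells: previously solid, now fluid
  fresh <- ctx$fluid & !state$cell_fluid
  if (any(fresh)) {
    nb_sum <- shift_mat(state$age * state$cell_fluid, 1, 0) +
      shift_mat(state$age * state$cell_fluid, -1, 0) +
      shift_mat(state$age * state$cell_fluid, 0, 1) +
      shift_mat(state$age * state$cell_fluid, 0, -1)
    nb_cnt <- shift_mat(state$cell_fluid + 0, 1, 0) +
      shift_mat(state$cell_fluid + 0, -1, 0) +
      shift_mat(state$cell_fluid + 0, 0, 1) +
      shift_mat(state$cell_fluid + 0, 0, -1)
    state$age[fresh] <- ifelse(nb_cnt[fresh] > 0,
                               nb_sum[fresh] / pmax(nb_cnt[fresh], 1), 0)
  }

  U <- full_field(state$u, ctx$u_presc, ctx$u_presc_idx, ctx$u_dead_idx)
  V <- full_field(state$v, ctx$v_presc, ctx$v_presc_idx, ctx$v_dead_idx)

  if (config$advection == "semilag") {
    ustar_adv <- semilag_field(U, U, V, grid, dt, "u", ctx$periodic)
    vstar_adv <- semilag_field(V, U, V, grid, dt, "v", ctx$periodic)
    adv_u <- (U - ustar_adv) / dt
    adv_v <- (V - vstar_adv) / dt
  } else {
    # donor-cell upwind with ghost-corrected tangential neighbours
    UE <- shift_mat(U, 1, 0); UW <- shift_mat(U, -1, 0)
    UN <- apply_ghosts(shift_mat(U, 0, 1), U, ctx$ghosts$u_n, h)
    US <- apply_ghosts(shift_mat(U, 0, -1), U, ctx$ghosts$u_s, h)
    # v averaged to u-faces
    vbar <- matrix(0, nx + 1, ny)
    vbar[2:nx, ] <- 0.25 * (V[1:(nx - 1), 1:ny] + V[1:(nx - 1), 2:(ny + 1)] +
                              V[2:nx, 1:ny] + V[2:nx, 2:(ny + 1)])
    adv_u <- ifelse(U > 0, U * (U - UW), U * (UE - U)) / h +
      ifelse(vbar > 0, vbar * (U - US), vbar * (UN - U)) / h

    VN <- shift_mat(V, 0, 1); VS <- shift_mat(V, 0, -1)
    VE <- apply_ghosts(shift_mat(V, 1, 0), V, ctx$ghosts$v_e, h)
    VW <- apply_ghosts(shift_mat(V, -1, 0), V, ctx$ghosts$v_w, h)
    ubar <- matrix(0, nx, ny + 1)
    ubar[, 2:ny] <- 0.25 * (U[1:nx, 1:(ny - 1)] + U[2:(nx + 1), 1:(ny - 1)] +
                              U[1:nx, 2:ny] + U[2:(nx + 1), 2:ny])
    adv_v <- ifelse(ubar > 0, ubar * (V - VW), ubar * (VE - V)) / h +
      ifelse(V > 0, V * (V - VS), V * (VN - V)) / h
  }

  # viscous term (explicit, ghost-corrected in the tangential direction)
  UE <- shift_mat(U, 1, 0); UW <- shift_mat(U, -1, 0)
  UN <- apply_ghosts(shift_mat(U, 0, 1), U, ctx$ghosts$u_n, h)
  US <- apply_ghosts(shift_mat(U, 0, -1), U, ctx$ghosts$u_s, h)
  lap_u <- (UE - 2 * U + UW + UN - 2 * U + US) / h^2
  VN <- shift_mat(V, 0, 1); VS <- shift_mat(V, 0, -1)
  VE <- apply_ghosts(shift_mat(V, 1, 0), V, ctx$ghosts$v_e, h)
  VW <- apply_ghosts(shift_mat(V, -1, 0), V, ctx$ghosts$v_w, h)
  lap_v <- (VE - 2 * V + VW + VN - 2 * V + VS) / h^2

  ustar <- U; vstar <- V
  ustar[ctx$u_fluid] <- U[ctx$u_fluid] +
    dt * (-adv_u[ctx$u_fluid] + nu * lap_u[ctx$u_fluid])
  vstar[ctx$v_fluid] <- V[ctx$v_fluid] +
    dt * (-adv_v[ctx$v_fluid] + nu * lap_v[ctx$v_fluid])
  # re-impose prescriptions
  ustar[ctx$u_presc_idx] <- ctx$u_presc[ctx$u_presc_idx]
  vstar[ctx$v_presc_idx] <- ctx$v_presc[ctx$v_presc_idx]

  # discrete compatibility: rescale open-orifice faces so the net boundary
  # flux balances the interior exactly
  div <- divergence_of(ustar, vstar, ctx)
  S <- sum(div[ctx$fluid]) * h^2
  ofl <- ctx$orifice_faces
  n_ofaces <- (if (is.null(ofl$u)) 0 else nrow(ofl$u)) +
    (if (is.null(ofl$v)) 0 else nrow(ofl$v))
  flux_applied <- c(0, 0)
  if (n_ofaces > 0) {
    delta <- -S / (n_ofaces * h)
    if (!is.null(ofl$u) && nrow(ofl$u) > 0) {
      ustar[ofl$u$idx] <- ustar[ofl$u$idx] + delta * ofl$u$sign
    }
    if (!is.null(ofl$v) && nrow(ofl$v) > 0) {
      vstar[ofl$v$idx] <- vstar[ofl$v$idx] + delta * ofl$v$sign
    }
    div <- divergence_of(ustar, vstar, ctx)
    # record realized orifice fluxes (outward-positive, m^2/s)
    for (k in 1:2) {
      f <- 0
      if (!is.null(ofl$u)) {
        su <- ofl$u[ofl$u$ori == k, ]
        if (nrow(su) > 0) f <- f + sum(ustar[su$idx] * su$sign) * h
      }
      if (!is.null(ofl$v)) {
        sv <- ofl$v[ofl$v$ori == k, ]
        if (nrow(sv) > 0) f <- f + sum(vstar[sv$idx] * sv$sign) * h
      }
      flux_applied[k] <- f
    }
  }

  # pressure projection
  pois <- ctx$poisson
  b <- -(rho / dt) * div[ctx$fluid]
  b <- b - mean(b)
  p_red <- Matrix::solve(pois$chol, b[pois$keep])
  p_vec <- numeric(pois$n)
  p_vec[pois$keep] <- as.numeric(p_red)
  res_hist <- numeric(0)
  for (it in seq_len(config$max_pressure_iterations)) {
    r <- b - as.numeric(pois$A %*% p_vec)
    div_res <- max(abs(r)) * dt / rho
    res_hist <- c(res_hist, div_res)
    if (div_res < config$div_tolerance) break
    dp <- Matrix::solve(pois$chol, r[pois$keep])
    p_vec[pois$keep] <- p_vec[pois$keep] + as.numeric(dp)
  }
  if (tail(res_hist, 1) >= config$div_tolerance) {
    abort(paste0("pressure solve failed to reach the divergence tolerance; ",
                 "residual history: ",
                 paste(signif(res_hist, 3), collapse = " ")))
  }
  P <- matrix(0, nx, ny)
  P[pois$cells] <- p_vec

  # velocity correction on interior fluid faces
  gfac <- dt / (rho * h)
  unew <- ustar; vnew <- vstar
  uf <- which(ctx$u_fluid)
  ij <- arrayInd(uf, c(nx + 1, ny))
  unew[uf] <- ustar[uf] - gfac * (P[cbind(ij[, 1], ij[, 2])] -
                                    P[cbind(ij[, 1] - 1L, ij[, 2])])
  vf <- which(ctx$v_fluid)
  ij <- arrayInd(vf, c(nx, ny + 1))
  vnew[vf] <- vstar[vf] - gfac * (P[cbind(ij[, 1], ij[, 2])] -
                                    P[cbind(ij[, 1], ij[, 2] - 1L)])

  div_after <- divergence_of(unew, vnew, ctx)
  div_max <- max(abs(div_after[ctx$fluid]))

  # age scalar: donor-cell transport with unit source, zero-age inflow
  age <- advect_age(state$age, unew, vnew, dt, ctx)

  state$u <- unew
  state$v <- vnew
  state$p <- P
  state$age <- age
  state$cell_fluid <- ctx$fluid
  state$time <- state$time + dt
  attr(state, "diagnostics") <- list(
    div_max = div_max, cfl = cfl,
    mitral_flux = flux_applied[1], aortic_flux = flux_applied[2],
    pressure_residuals = res_hist)
  state
}

# semi-Lagrangian advected field (bilinear backtrace); kind "u" or "v"
semilag_field <- function(F0, U, V, grid, dt, kind, periodic = FALSE) {
  nx <- grid$nx; ny <- grid$ny; h <- grid$h
  if (kind == "u") {
    X <- matrix(rep(grid$xf, ny), nx + 1, ny)
    Y <- matrix(rep(grid$yc, each = nx + 1), nx + 1, ny)
    uu <- F0
    vv <- matrix(0, nx + 1, ny)
    vv[2:nx, ] <- 0.25 * (V[1:(nx - 1), 1:ny] + V[1:(nx - 1), 2:(ny + 1)] +
                            V[2:nx, 1:ny] + V[2:nx, 2:(ny + 1)])
    if (periodic) {
      vv[1, ] <- 0.25 * (V[nx, 1:ny] + V[nx, 2:(ny + 1)] + V[1, 1:ny] + V[1, 2:(ny + 1)])
      vv[nx + 1, ] <- vv[1, ]
    }
  } else {
    X <- matrix(rep(grid$xc, ny + 1), nx, ny + 1)
    Y <- matrix(rep(grid$yf, each = nx), nx, ny + 1)
    vv <- F0
    uu <- matrix(0, nx, ny + 1)
    uu[, 2:ny] <- 0.25 * (U[1:nx, 1:(ny - 1)] + U[2:(nx + 1), 1:(ny - 1)] +
                            U[1:nx, 2:ny] + U[2:(nx + 1), 2:ny])
    if (periodic) {
      uu[, 1] <- 0.25 * (U[1:nx, ny] + U[2:(nx + 1), ny] + U[1:nx, 1] + U[2:(nx + 1), 1])
      uu[, ny + 1] <- uu[, 1]
    }
  }
  xd <- X - uu * dt
  yd <- Y - vv * dt
  sample_staggered(F0, xd, yd, grid, kind, periodic)
}

# bilinear sample of a staggered field at arbitrary points
sample_staggered <- function(F0, xq, yq, grid, kind, periodic = FALSE) {
  nx <- grid$nx; ny <- grid$ny; h <- grid$h
  if (kind == "u") {
    gx <- (xq - grid$origin[1]) / h + 1
    gy <- (yq - grid$origin[2]) / h + 0.5
    nrx <- nx + 1; nry <- ny
  } else if (kind == "v") {
    gx <- (xq - grid$origin[1]) / h + 0.5
    gy <- (yq - grid$origin[2]) / h + 1
    nrx <- nx; nry <- ny + 1
  } else {  # cell-centred
    gx <- (xq - grid$origin[1]) / h + 0.5
    gy <- (yq - grid$origin[2]) / h + 0.5
    nrx <- nx; nry <- ny
  }
  if (periodic) {
    i0 <- floor(gx); j0 <- floor(gy)
    fx <- gx - i0; fy <- gy - j0
    wrap <- function(k, n) ((k - 1) %% n) + 1
    i0w <- wrap(i0, nx); i1w <- wrap(i0 + 1, nx)
    j0w <- wrap(j0, ny); j1w <- wrap(j0 + 1, ny)
    # for periodic grids the staggered arrays repeat with period nx, ny
    i0w <- pmin(i0w, nrx); i1w <- pmin(i1w, nrx)
    j0w <- pmin(j0w, nry); j1w <- pmin(j1w, nry)
  } else {
    gx <- pmin(pmax(gx, 1), nrx)
    gy <- pmin(pmax(gy, 1), nry)
    i0 <- pmin(floor(gx), nrx - 1); j0 <- pmin(floor(gy), nry - 1)
    fx <- gx - i0; fy <- gy - j0
    i0w <- i0; i1w <- i0 + 1; j0w <- j0; j1w <- j0 + 1
  }
  F0[cbind(c(i0w), c(j0w))] * (1 - fx) * (1 - fy) +
    F0[cbind(c(i1w), c(j0w))] * fx * (1 - fy) +
    F0[cbind(c(i0w), c(j1w))] * (1 - fx) * fy +
    F0[cbind(c(i1w), c(j1w))] * fx * fy
}

#' Advance the flow-age scalar
#'
#' Solves `dT/dt + u . grad T = 1` by donor-cell upwind differencing with
#' zero age imposed on inflow orifice faces. In stagnant fluid the field
#' grows by exactly `dt` per step.
#'
#' @param age Cell-centred age field (s).
#' @param U,V Face velocity fields including boundary prescriptions (m/s).
#' @param dt Time step (s).
#' @param ctx Step context (carries masks and inflow-face lists).
#' @return Updated age field (s), non-negative, zero in solid cells.
#' @export
advect_age <- function(age, U, V, dt, ctx) {
  nx <- ctx$grid$nx; ny <- ctx$grid$ny; h <- ctx$grid$h
  fl <- ctx$fluid
  T0 <- age
  TE <- shift_mat(T0, 1, 0); TW <- shift_mat(T0, -1, 0)
  TN <- shift_mat(T0, 0, 1); TS <- shift_mat(T0, 0, -1)
  # zero-gradient into solid neighbours
  flE <- shift_mat(fl + 0, 1, 0) > 0; flW <- shift_mat(fl + 0, -1, 0) > 0
  flN <- shift_mat(fl + 0, 0, 1) > 0; flS <- shift_mat(fl + 0, 0, -1) > 0
  TE[!flE] <- T0[!flE]; TW[!flW] <- T0[!flW]
  TN[!flN] <- T0[!flN]; TS[!flS] <- T0[!flS]
  # zero-age at inflow orifice neighbours
  inf <- ctx$inflow_cells
  if (!is.null(inf)) {
    if (length(inf$W)) TW[inf$W] <- 0
    if (length(inf$E)) TE[inf$E] <- 0
    if (length(inf$S)) TS[inf$S] <- 0
    if (length(inf$N)) TN[inf$N] <- 0
  }
  uc <- 0.5 * (U[1:nx, , drop = FALSE] + U[2:(nx + 1), , drop = FALSE])
  vc <- 0.5 * (V[, 1:ny, drop = FALSE] + V[, 2:(ny + 1), drop = FALSE])
  dTdx <- ifelse(uc > 0, (T0 - TW), (TE - T0)) / h
  dTdy <- ifelse(vc > 0, (T0 - TS), (TN - T0)) / h
  Tn <- T0 + dt * (1 - uc * dTdx - vc * dTdy)
  Tn[!fl] <- 0
  Tn[Tn < 0] <- 0
  Tn
}
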