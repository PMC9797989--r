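# unit-level solver checks; the heavier verification cases (Poiseuille
# convergence, full-cycle mass balance) live in the acceptance suite

test_that("orifice fluxes follow the cavity-area rate with phase gating", {
  s <- quick_series()
  dm <- interpolate_motion(s, dt = 1e-3)
  # during contraction the aortic orifice carries the (positive) outflow
  f_sys <- flux_from_volume(dm, 0.12)
  expect_gt(f_sys$aortic_flux, 0)
  expect_equal(f_sys$mitral_flux, 0)
  # during filling the mitral orifice carries the inflow
  f_dia <- flux_from_volume(dm, 0.55)
  expect_gt(f_dia$mitral_flux, 0)
  expect_equal(f_dia$aortic_flux, 0)
  # wrapping, not an error, outside the cycle
  expect_equal(flux_from_volume(dm, 0.12 + s$cycle_duration)$aortic_flux,
               f_sys$aortic_flux)
})

test_that("cosine area waveform reproduces its analytic derivative", {
  # dense trajectory built directly from analytic motion: circle with
  # radius r(t) chosen so area(t) = A0 + B cos(2 pi t)
  n_pts <- 60; tc <- 1
  A0 <- pi * 400; B <- 100
  times <- seq(0, tc, by = 2e-3)
  base <- circle_boundary(r = 1, n = n_pts)
  r_t <- sqrt((A0 + B * cos(2 * pi * times)) / pi)
  xs <- outer(base[, 1], r_t)
  ys <- outer(base[, 2], r_t)
  s <- structure(list(xs = xs, ys = ys, times = times,
                      areas = A0 + B * cos(2 * pi * times),
                      mitral_idx = integer(0), aortic_idx = integer(0),
                      cycle_duration = tc, params = NULL, aux = NULL,
                      device = NULL), class = "motion_series")
  dm <- interpolate_motion(s, dt = 1e-3)
  tq <- c(0.1, 0.23, 0.57, 0.81)
  got <- dm$dareadt_fun(tq)
  # the n-gon boundary carries the polygon's area, a fixed fraction of the
  # disc's; the derivative scales by the same factor
  cn <- n_pts / 2 * sin(2 * pi / n_pts)
  want <- (cn / pi) * (-2 * pi * B * sin(2 * pi * tq))
  expect_equal(got, want, tolerance = 1e-6)
})

test_that("quiescent fluid with stationary walls stays at rest", {
  H <- 0.01
  dom <- channel_domain(0.02, H, H / 16, profile = function(s) 0)
  cfg <- solver_config(dt = 1e-3, grid_h = H / 16)
  st <- vimflow:::new_flow_state(dom$grid)
  ctx <- vimflow:::build_context(dom, 0, cfg)
  st$cell_fluid <- ctx$fluid
  st2 <- step_flow(st, ctx, fluid_properties(), cfg)
  expect_equal(max(abs(st2$u)), 0)
  expect_equal(max(abs(st2$v)), 0)
  expect_lt(diff(range(st2$p[ctx$fluid])), 1e-12)
})

test_that("CFL violations are rejected with advice", {
  H <- 0.01
  dom <- channel_domain(0.02, H, H / 16, profile = function(s) 0)
  cfg <- solver_config(dt = 1e-2, grid_h = H / 16)
  st <- vimflow:::new_flow_state(dom$grid)
  ctx <- vimflow:::build_context(dom, 0, cfg)
  st$cell_fluid <- ctx$fluid
  st$u[] <- 1   # 1 m/s at dt = 10 ms, h = 0.625 mm -> CFL 16
  expect_error(step_flow(st, ctx, fluid_properties(), cfg), "CFL")
})

test_that("age grows by exactly dt per step in stagnant fluid", {
  H <- 0.01
  dom <- channel_domain(0.02, H, H / 16, profile = function(s) 0)
  cfg <- solver_config(dt = 1e-3, grid_h = H / 16)
  ctx <- vimflow:::build_context(dom, 0, cfg)
  age <- matrix(0, dom$grid$nx, dom$grid$ny)
  U <- matrix(0, dom$grid$nx + 1, dom$grid$ny)
  V <- matrix(0, dom$grid$nx, dom$grid$ny + 1)
  for (k in 1:7) age <- advect_age(age, U, V, cfg$dt, ctx)
  vals <- age[ctx$fluid]
  expect_true(all(vals == vals[1]))
  expect_equal(vals[1], sum(rep(cfg$dt, 7)))
})

test_that("steady plug flow transports age as T = L / U", {
  H <- 0.01; U0 <- 0.2; h <- H / 32
  dom <- channel_domain(0.04, H, h, profile = function(s) U0)
  cfg <- solver_config(dt = 5e-4, grid_h = h)
  ctx <- vimflow:::build_context(dom, 0, cfg)
  # uniform velocity field imposed directly (slip walls); enough steps for
  # the age to reach steady state over the channel length
  U <- matrix(U0, dom$grid$nx + 1, dom$grid$ny)
  V <- matrix(0, dom$grid$nx, dom$grid$ny + 1)
  age <- matrix(0, dom$grid$nx, dom$grid$ny)
  n_steps <- ceiling(2 * 0.04 / U0 / cfg$dt)
  for (k in seq_len(n_steps)) age <- advect_age(age, U, V, cfg$dt, ctx)
  L <- 0.03
  i <- which.min(abs(dom$grid$xc - L))
  j <- which(ctx$fluid[i, ])
  j <- j[ceiling(length(j) / 2)]
  expect_equal(age[i, j], L / U0, tolerance = 0.05)
  # age increases monotonically along the streamwise direction
  mid <- age[cbind(1:dom$grid$nx, j)]
  infl <- which(ctx$fluid[, j])
  expect_true(all(diff(mid[infl]) >= -1e-9))
})

test_that("probe pressures are exact on linear fields and AV-referenced", {
  H <- 0.01
  dom <- channel_domain(0.03, H, H / 16, profile = function(s) 0)
  st <- vimflow:::new_flow_state(dom$grid)
  ctx <- vimflow:::build_context(dom, 0, solver_config(grid_h = H / 16))
  st$cell_fluid <- ctx$fluid
  alpha <- 250
  st$p <- outer(dom$grid$xc, rep(1, dom$grid$ny)) * alpha
  ymid <- (dom$channel$y0 + dom$channel$y1) / 2 * 1000
  probes <- tibble::tibble(probe = c("AV", "VC_proximal", "VC_distal"),
                           x = c(5, 10, 20), y = rep(ymid, 3))
  ps <- sample_probe_pressure(st, probes)
  expect_equal(ps$pressure[ps$probe == "AV"], 0)
  got <- ps$pressure[ps$probe == "VC_proximal"] -
    ps$pressure[ps$probe == "VC_distal"]
  expect_equal(got, -alpha * 0.010, tolerance = 1e-9)
  # uniform field: all gauge values zero
  st$p[] <- 777
  ps2 <- sample_probe_pressure(st, probes)
  expect_equal(ps2$pressure, rep(0, 3))
  # a probe in the wall is an error naming it
  bad <- tibble::tibble(probe = "AV", x = 5, y = 0.01)
  expect_error(sample_probe_pressure(st, bad), "AV")
})

test_that("a uniform velocity shift translates the periodic solution", {
  n <- 32; h <- 1e-3
  dom <- periodic_domain(n, h)
  props <- fluid_properties()
  dt <- 2e-4
  set.seed(5)
  # smooth divergence-free-ish initial field (projection enforces the rest)
  kx <- 2 * pi / (n * h)
  X <- outer((seq_len(n) - 1) * h, rep(1, n))
  Y <- t(X)
  u0 <- 0.2 * sin(kx * X) * cos(kx * Y)
  v0 <- -0.2 * cos(kx * X) * sin(kx * Y)
  # shift chosen so U dt is an exact multiple of h (bitwise index shift)
  Ushift <- h / dt * 2    # 2 cells per step
  a <- list(u = u0, v = v0)
  b <- list(u = u0 + Ushift, v = v0)
  for (k in 1:10) {
    a <- step_periodic(a$u, a$v, dom$grid, props, dt)
    b <- step_periodic(b$u, b$v, dom$grid, props, dt)
  }
  # the boosted solution is the unboosted one advected by U t:
  # b(x) = a(x - Ut) + U, up to the O(U |grad u| dt^2) error of evaluating
  # the semi-Lagrangian departure velocity at the arrival point
  shift_cells <- (2 * 10) %% n
  idx <- ((seq_len(n) - 1 - shift_cells) %% n) + 1
  scale <- max(abs(a$u))
  expect_lt(max(abs(b$u - (a$u[idx, ] + Ushift))), 0.02 * scale)
  expect_lt(max(abs(b$v - a$v[idx, ])), 0.02 * scale)
  # the agreement is specific to the correct shift
  idx_wrong <- ((seq_len(n) - 1 + shift_cells) %% n) + 1
  expect_gt(max(abs(b$u - (a$u[idx_wrong, ] + Ushift))), 0.5 * scale)
})

test_that("impulsive flow past the frame stays bounded and divergence-free", {
  s <- quick_series()
  sv <- embed_valve(s, valve_frame_spec(protrusion_fraction = 0.5))
  dm <- interpolate_motion(sv, dt = 2e-3)
  cfg <- solver_config(dt = 2e-3, grid_h = 2e-3, snapshot_stride = 1e9)
  run <- run_cycles(dm, fluid_properties(), cfg, probes = NULL,
                    n_cycles = 1, wall_stride = 1e9)
  expect_lt(max(run$fluxes$div_max), cfg$div_tolerance)
  ke <- max(abs(run$state$u))
  expect_lt(ke, 5)     # bounded velocity after a full cycle
  expect_true(all(run$state$age >= 0))
})

test_that("runs are bitwise deterministic and n_cycles = 0 is empty", {
  s <- quick_series()
  sv <- embed_valve(s, valve_frame_spec(protrusion_fraction = 0.3))
  dm <- interpolate_motion(sv, dt = 2e-3)
  cfg <- solver_config(dt = 2e-3, grid_h = 2e-3, snapshot_stride = 1e9)
  pr <- probe_set(sv)
  r0 <- run_cycles(dm, fluid_properties(), cfg, probes = pr, n_cycles = 0)
  expect_equal(nrow(r0$fluxes), 0)
  expect_equal(r0$state$time, 0)
  r1 <- run_cycles(dm, fluid_properties(), cfg, probes = pr, n_cycles = 1,
                   wall_stride = 4L)
  r2 <- run_cycles(dm, fluid_properties(), cfg, probes = pr, n_cycles = 1,
                   wall_stride = 4L)
  expect_identical(r1$probe_series$pressure, r2$probe_series$pressure)
  expect_identical(r1$wall_series$tau_x, r2$wall_series$tau_x)
})
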