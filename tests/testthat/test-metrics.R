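test_that("OSI reaches its analytic extremes", {
  tt <- seq(0, 1, length.out = 1001)
  rec <- make_wss_record(tt, matrix(sin(2 * pi * tt), 1), matrix(0, 1, 1001))
  expect_equal(osi(rec)$osi, 0.5, tolerance = 1e-3)
  rec2 <- make_wss_record(tt, matrix(5, 1, 1001), matrix(0, 1, 1001))
  expect_equal(osi(rec2)$osi, 0)
  # all-zero shear: defined as 0 with a flag
  rec3 <- make_wss_record(tt, matrix(0, 1, 1001), matrix(0, 1, 1001))
  o3 <- osi(rec3)
  expect_equal(o3$osi, 0)
  expect_true(o3$zero_shear)
})

test_that("OSI of asymmetric square shear matches numerical quadrature", {
  tt <- seq(0, 1, length.out = 2001)
  tau <- ifelse(tt %% 1 < 0.5, 2, -1)
  rec <- make_wss_record(tt, matrix(tau, 1), matrix(0, 1, length(tt)))
  # independent trapezoid evaluation of the definition
  trap <- function(y) sum(diff(tt) * (head(y, -1) + tail(y, -1)) / 2)
  want <- 0.5 * (1 - abs(trap(tau)) / trap(abs(tau)))
  expect_equal(osi(rec)$osi, want, tolerance = 1e-9)
  expect_true(osi(rec)$osi > 0 && osi(rec)$osi < 0.5)
})

test_that("OSI stays in [0, 0.5] on random records", {
  set.seed(9)
  for (rep in 1:5) {
    tt <- seq(0, 2, length.out = 301)
    rec <- make_wss_record(tt, matrix(rnorm(5 * 301), 5),
                           matrix(rnorm(5 * 301), 5))
    o <- osi(rec)$osi
    expect_true(all(o >= 0 & o <= 0.5))
  }
})

test_that("WSS statistics agree with brute-force loops", {
  tt <- seq(0, 1, length.out = 101)
  rec <- make_wss_record(tt, matrix(7, 3, 101), matrix(0, 3, 101))
  ws <- wss_statistics(rec)
  expect_equal(ws$max_wss, 7)
  expect_equal(ws$mean_wss, 7)
  expect_equal(ws$max_surface_avg_wss, 7)

  # single sample spiking at one instant
  tx <- matrix(0, 4, 101); tx[2, 51] <- 100
  rec2 <- make_wss_record(tt, tx, matrix(0, 4, 101))
  ws2 <- wss_statistics(rec2)
  expect_equal(ws2$max_wss, 100)
  expect_equal(ws2$max_surface_avg_wss, 100 / 4)

  set.seed(4)
  tx <- matrix(rnorm(5 * 101), 5); ty <- matrix(rnorm(5 * 101), 5)
  rec3 <- make_wss_record(tt, tx, ty)
  ws3 <- wss_statistics(rec3)
  mag <- sqrt(tx^2 + ty^2)
  mx <- -Inf; sm <- 0; surf <- rep(0, 101)
  for (i in 1:5) for (j in 1:101) {
    mx <- max(mx, mag[i, j]); sm <- sm + mag[i, j]
    surf[j] <- surf[j] + mag[i, j] / 5
  }
  expect_equal(ws3$max_wss, mx)
  expect_equal(ws3$mean_wss, sm / (5 * 101))
  expect_equal(ws3$max_surface_avg_wss, max(surf))
  expect_lte(ws3$mean_wss, ws3$max_wss)
  expect_lte(ws3$max_surface_avg_wss, ws3$max_wss)
})

test_that("exposure time measures threshold exceedance and is monotone", {
  tt <- seq(0, 0.3, length.out = 301)
  rec <- make_wss_record(tt, matrix(60, 1, 301), matrix(0, 1, 301))
  expect_equal(exposure_time(rec, 50), 0.3, tolerance = 0.01)
  expect_equal(exposure_time(rec, 70), 0)
  # 40% duty square wave at 80/10 Pa over 1 s, threshold 50 -> 0.4 s
  tt2 <- seq(0, 1 - 1e-3, length.out = 1000)
  tau <- ifelse(tt2 %% 0.1 < 0.04, 80, 10)
  rec2 <- make_wss_record(tt2, matrix(tau, 1), matrix(0, 1, 1000))
  counted <- sum(tau > 50) * (tt2[2] - tt2[1])
  expect_equal(exposure_time(rec2, 50), counted, tolerance = 1e-9)
  expect_equal(exposure_time(rec2, 50), 0.4, tolerance = 0.01)
  # monotone non-increasing in the threshold
  thr <- c(5, 20, 50, 79, 81)
  ex <- vapply(thr, function(x) exposure_time(rec2, x), numeric(1))
  expect_true(all(diff(ex) <= 1e-12))
  expect_error(exposure_time(rec2, -1), "positive")
})

test_that("activation check interpolates the threshold curve log-log", {
  curve <- activation_curve(data.frame(exposure_s = c(0.01, 0.1, 1),
                                       wss_pa = c(200, 80, 30)))
  # on a vertex
  chk <- activation_check(80, 0.1, curve)
  expect_equal(chk$margin, 1)
  expect_equal(chk$flag, "above")
  # half the threshold
  chk2 <- activation_check(40, 0.1, curve)
  expect_equal(chk2$margin, 0.5)
  expect_equal(chk2$flag, "below")
  # mid-interval: hand log-log interpolation
  e <- exp(mean(log(c(0.01, 0.1))))
  want <- exp(mean(log(c(200, 80))))
  expect_equal(activation_threshold_at(curve, e), want, tolerance = 1e-12)
  # out-of-range exposure: nearest endpoint with warning
  expect_warning(v <- activation_threshold_at(curve, 10), "endpoint")
  expect_equal(v, 30)
})

test_that("pressure gradients convert and average correctly", {
  # constant 133.322 Pa over systole -> exactly 1 mmHg
  tt <- seq(0, 0.3, length.out = 31)
  ps <- tibble::tibble(
    time = rep(tt, 2),
    probe = rep(c("VC_proximal", "VC_distal"), each = 31),
    pressure = c(rep(133.322, 31), rep(0, 31)))
  pg <- pressure_gradient_lvot(ps, c(0, 0.3))
  expect_equal(pg$max_mmHg, 1)
  expect_equal(pg$mean_mmHg, 1)
  # triangular ramp 0 -> X -> 0: mean X/2, max X
  X <- 400
  ramp <- X * (1 - abs(2 * tt / 0.3 - 1))
  ps2 <- tibble::tibble(time = rep(tt, 2),
                        probe = rep(c("VC_proximal", "VC_distal"), each = 31),
                        pressure = c(ramp, rep(0, 31)))
  pg2 <- pressure_gradient_lvot(ps2, c(0, 0.3))
  expect_equal(pg2$max_mmHg, X / 133.322)
  expect_equal(pg2$mean_mmHg, X / 2 / 133.322, tolerance = 0.02)
  expect_lte(pg2$mean_mmHg, pg2$max_mmHg)
  # independent trapezoid recomputation oracle
  trap <- sum(diff(tt) * (head(ramp, -1) + tail(ramp, -1)) / 2) / 0.3
  expect_equal(pg2$mean_mmHg, trap / 133.322, tolerance = 1e-12)
  expect_error(pressure_gradient_lvot(ps2, c(10, 11)), "window")
})

test_that("LVOT obstruction classification follows the clinical rule", {
  expect_equal(classify_lvoto(80.6), "excessive")
  expect_equal(classify_lvoto(19.5, baseline_pg = 12), "acceptable")
  expect_equal(classify_lvoto(45, baseline_pg = 35), "excessive")   # delta = 10
  expect_equal(classify_lvoto(50), "acceptable")                    # strict >
  expect_equal(classify_lvoto(50.01), "excessive")
  expect_equal(classify_lvoto(49.99, baseline_pg = 40.01), "acceptable")
  expect_error(classify_lvoto(-5), "non-negative")
  expect_error(classify_lvoto(20, baseline_pg = -1), "non-negative")
})

test_that("residence-time statistics reduce to masked means", {
  grid <- vimflow:::make_grid2d(c(0, 0), 1e-3, 8, 8)
  st <- vimflow:::new_flow_state(grid)
  st$age[] <- 1.51
  b <- brt_statistics(st, NULL, cycle_duration = 1.0)
  expect_equal(b$mean_s, 1.51)
  expect_equal(b$mean_cycles, 1.51)
  # masked recomputation oracle on a random field and region
  set.seed(6)
  st$age[] <- runif(64)
  region <- matrix(runif(64) > 0.5, 8, 8)
  b2 <- brt_statistics(st, region, cycle_duration = 0.8)
  expect_equal(b2$mean_s, mean(st$age[region]))
  expect_equal(b2$max_cycles, max(st$age[region]) / 0.8)
  expect_error(brt_statistics(st, matrix(FALSE, 8, 8), 1), "empty")
})
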