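test_that("registering a boundary to itself yields a near-zero field", {
  src <- circle_boundary()
  fit <- ffd_register(src, src, tracking_config(max_iterations = 40))
  expect_lt(max(abs(eval_displacement(fit$field, src))), 1e-3)
})

test_that("a pure translation is recovered by registration", {
  src <- circle_boundary()
  tgt <- sweep(src, 2, c(3, -2), "+")
  fit <- ffd_register(src, tgt,
                      tracking_config(control_spacing = 12, max_iterations = 150))
  d <- colMeans(eval_displacement(fit$field, src))
  expect_equal(d, c(3, -2), tolerance = 0.2, ignore_attr = TRUE)
})

test_that("registration objective is non-increasing within each level", {
  src <- circle_boundary()
  tgt <- src * 0.9
  fit <- suppressWarnings(
    ffd_register(src, tgt, tracking_config(max_iterations = 80)))
  for (tr in fit$objective_by_level) {
    expect_true(all(diff(tr) <= 1e-12))
  }
  # and the registration improves the Hausdorff distance
  hd_pre <- hausdorff_distance(src, tgt)
  hd_post <- hausdorff_distance(apply_displacement(fit$field, src), tgt)
  expect_lt(hd_post, hd_pre)
})

test_that("non-overlapping extents are rejected", {
  src <- circle_boundary(r = 5)
  expect_error(ffd_register(src, sweep(src, 2, c(100, 100), "+")),
               "overlap")
})

test_that("hausdorff distance satisfies its definition", {
  A <- circle_boundary(n = 40)
  expect_lt(hausdorff_distance(A, A), 1e-6)   # zero up to float tolerance
  expect_equal(hausdorff_distance(matrix(c(0, 0), 1), matrix(c(3, 4), 1)), 5)
  expect_error(hausdorff_distance(A[0, , drop = FALSE], A), "non-empty")
  # brute-force double-loop oracle on random sets
  set.seed(11)
  for (rep in 1:3) {
    A <- matrix(rnorm(100), ncol = 2)
    B <- matrix(rnorm(80), ncol = 2)
    expect_equal(hausdorff_distance(A, B), hausdorff_bruteforce(A, B),
                 tolerance = 1e-8)
    expect_equal(hausdorff_distance(A, B), hausdorff_distance(B, A))
  }
})

test_that("boundary propagation composes displacement fields", {
  init <- circle_boundary()
  geom <- vimflow:::make_field_geom(list(init), 12)
  zero <- displacement_field(geom$origin, 12,
                             matrix(0, geom$gx, geom$gy),
                             matrix(0, geom$gx, geom$gy))
  prop <- propagate_boundary(init, list(zero, zero))
  expect_equal(frame_boundary(prop, 3), init, ignore_attr = TRUE)

  shift <- displacement_field(geom$origin, 12,
                              matrix(2, geom$gx, geom$gy),
                              matrix(-1, geom$gx, geom$gy))
  prop2 <- propagate_boundary(init, list(shift))
  expect_equal(frame_boundary(prop2, 2),
               sweep(init, 2, c(2, -1), "+"), tolerance = 1e-9,
               ignore_attr = TRUE)

  far <- displacement_field(c(500, 500), 12,
                            matrix(0, 8, 8), matrix(0, 8, 8))
  expect_error(propagate_boundary(init, list(far)), "frame 2")
})

test_that("FFD-generated deformations are recovered below 0.5 mm Hausdorff", {
  src <- circle_boundary()
  geom_gt <- vimflow:::make_field_geom(list(src), 16)
  set.seed(11)
  gt <- displacement_field(geom_gt$origin, 16,
                           matrix(rnorm(geom_gt$gx * geom_gt$gy, 0, 1.5),
                                  geom_gt$gx, geom_gt$gy),
                           matrix(rnorm(geom_gt$gx * geom_gt$gy, 0, 1.5),
                                  geom_gt$gx, geom_gt$gy))
  tgt <- apply_displacement(gt, src)
  fit <- suppressWarnings(ffd_register(
    src, tgt, tracking_config(control_spacing = 8, max_iterations = 200)))
  hd <- hausdorff_distance(apply_displacement(fit$field, src), tgt)
  expect_lt(hd, 0.5)
})

test_that("frame-to-frame tracking stays within the in-vivo error scale", {
  s <- generate_anatomy(lv_shape_params(n_frames = 6))
  tk <- suppressWarnings(track_series(
    s, tracking_config(control_spacing = 6, max_iterations = 80)))
  expect_lt(max(tk$report$hausdorff_mm), 2.0)
  expect_equal(nrow(tk$report), length(s$times))
})

test_that("temporal interpolation passes through frames and is periodic", {
  s <- quick_series()
  dm <- interpolate_motion(s, dt = 1e-3)
  k <- 4L
  expect_identical(boundary_at(dm, s$times[k]), frame_boundary(s, k))
  expect_identical(boundary_at(dm, 0.1), boundary_at(dm, 0.1 + s$cycle_duration))
  expect_error(interpolate_motion(s, dt = -1), "dt")
  # dense area curve preserves the stroke area of the sparse frames
  stroke_sparse <- max(s$areas) - min(s$areas)
  stroke_dense <- max(dm$areas) - min(dm$areas)
  expect_equal(stroke_dense, stroke_sparse, tolerance = 0.05)
  # cycle-integrated area rate vanishes
  expect_lt(abs(sum(dm$dareadt_fun(dm$times)) * dm$dt), 1e-6 * max(dm$areas))
})

test_that("closed-form harmonic motion is reproduced between frames", {
  # single-harmonic translation sampled densely: the periodic cubic spline
  # reproduces the analytic motion to fourth order in the knot spacing
  n_pts <- 30
  base <- circle_boundary(r = 10, n = n_pts)
  times <- seq(0, 1, by = 0.005)
  xs <- vapply(times, function(t) base[, 1] + 3 * sin(2 * pi * t),
               numeric(n_pts))
  xs[, ncol(xs)] <- xs[, 1]        # exact periodicity at the seam
  ys <- vapply(times, function(t) base[, 2], numeric(n_pts))
  s <- structure(list(xs = xs, ys = ys, times = times,
                      areas = rep(pi * 100, length(times)),
                      mitral_idx = integer(0), aortic_idx = integer(0),
                      cycle_duration = 1, params = NULL, aux = NULL,
                      device = NULL), class = "motion_series")
  dm <- interpolate_motion(s, dt = 0.001)
  tq <- 0.3141                                  # off every knot grid
  got <- cbind(vapply(dm$vx_funs, function(f) f(tq), numeric(1)),
               vapply(dm$vy_funs, function(f) f(tq), numeric(1)))
  want_x <- base[, 1] + 3 * sin(2 * pi * tq)
  expect_equal(got[, 1], want_x, tolerance = 1e-6)
  expect_equal(got[, 2], base[, 2], tolerance = 1e-9)
})

test_that("mask contours can drive registration", {
  s <- quick_series()
  stack <- make_masks(s, 0.5)
  c1 <- mask_contour(stack, 1)
  c2 <- mask_contour(stack, 3)
  fit <- suppressWarnings(ffd_register(c1, c2, tracking_config(
    control_spacing = 8, max_iterations = 60)))
  hd_post <- hausdorff_distance(apply_displacement(fit$field, c1), c2)
  expect_lt(hd_post, hausdorff_distance(c1, c2))
})

test_that("displacement fields round-trip through JSON", {
  geom <- vimflow:::make_field_geom(list(circle_boundary()), 10)
  set.seed(2)
  f <- displacement_field(geom$origin, 10,
                          matrix(rnorm(geom$gx * geom$gy), geom$gx, geom$gy),
                          matrix(rnorm(geom$gx * geom$gy), geom$gx, geom$gy))
  path <- withr::local_tempfile(fileext = ".json")
  write_displacement_field_json(f, path)
  f2 <- read_displacement_field_json(path)
  pts <- circle_boundary(r = 10)
  expect_equal(eval_displacement(f2, pts), eval_displacement(f, pts),
               tolerance = 1e-12)
})
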