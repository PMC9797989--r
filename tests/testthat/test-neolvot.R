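test_that("annulus plane fitting recovers exact and noisy planes", {
  # landmarks on z = 0
  ring <- cbind(cos(seq(0, 2 * pi, length.out = 9)[-9]) * 10,
                sin(seq(0, 2 * pi, length.out = 9)[-9]) * 10, 0)
  mesh <- surface_mesh3d(rbind(ring, c(0, 0, 5), c(0, 0, 6), c(1, 0, 6)),
                         matrix(c(1, 2, 9, 2, 3, 9, 3, 4, 10), 3, 3, byrow = TRUE),
                         annulus_landmarks = 1:8, lvot_outlet_landmarks = 9:11)
  pl <- fit_annulus_plane(mesh)
  expect_equal(abs(pl$normal[3]), 1, tolerance = 1e-12)
  expect_equal(sum(pl$point * pl$normal), 0, tolerance = 1e-9)

  # tilted plane with normal n0, exact landmarks
  n0 <- c(1, 2, 3) / sqrt(14)
  e1 <- c(-2, 1, 0) / sqrt(5)
  e2 <- c(n0[2] * e1[3] - n0[3] * e1[2], n0[3] * e1[1] - n0[1] * e1[3],
          n0[1] * e1[2] - n0[2] * e1[1])
  th <- seq(0, 2 * pi, length.out = 13)[-13]
  lm <- t(vapply(th, function(a) 10 * cos(a) * e1 + 10 * sin(a) * e2,
                 numeric(3)))
  mesh2 <- surface_mesh3d(rbind(lm, 5 * n0, 6 * n0, 6 * n0 + e1),
                          matrix(c(1, 2, 13, 2, 3, 13, 3, 4, 14), 3, 3,
                                 byrow = TRUE),
                          1:12, 13:15)
  pl2 <- fit_annulus_plane(mesh2)
  expect_lt(acos(abs(sum(pl2$normal * n0))), 1e-6)

  # noisy landmarks: normal within 1 degree
  set.seed(3)
  mesh3 <- mesh2
  mesh3$vertices[1:12, ] <- lm + matrix(rnorm(36, 0, 0.1), 12, 3)
  pl3 <- fit_annulus_plane(mesh3)
  expect_lt(acos(abs(sum(pl3$normal * n0))) * 180 / pi, 1)

  bad <- surface_mesh3d(rbind(cbind(1:4, 0, 0), c(0, 1, 5), c(0, 2, 5), c(1, 2, 5)),
                        matrix(c(1, 2, 5, 2, 3, 6, 3, 4, 7), 3, 3, byrow = TRUE),
                        1:4, 5:7)
  expect_error(fit_annulus_plane(bad), "collinear")
})

test_that("neo-LVOT axis follows the free-lumen centroid", {
  p <- lv_shape_params(lvot_width = 20, basal_diameter = 54)
  ph <- generate_3d_phantom(p, valve_frame_spec(diameter = 16, height = 12,
                                                protrusion_fraction = 0),
                            n_around = 96)
  ax <- neo_lvot_axis(ph$mesh, ph$device)
  expect_equal(abs(ax$direction[3]), 1, tolerance = 1e-6)
  # a device biting into the +x side pushes the free-lumen centroid to -x,
  # tilting the axis toward +x as it runs to the outlet centroid at 0
  ph2 <- generate_3d_phantom(p, valve_frame_spec(diameter = 16, height = 12,
                                                 protrusion_fraction = 0.7),
                             n_around = 96)
  ax2 <- neo_lvot_axis(ph2$mesh, ph2$device)
  expect_lt(ax2$point[1], -1)     # start centroid displaced away from device
  expect_gt(ax2$direction[1], 0)
})

test_that("minimal area decreases with protrusion and is rigid-invariant", {
  p <- lv_shape_params(lvot_width = 20, basal_diameter = 54)
  areas <- vapply(c(0.2, 0.5, 0.8), function(pf) {
    ph <- generate_3d_phantom(p, valve_frame_spec(diameter = 16, height = 12,
                                                  protrusion_fraction = pf),
                              n_around = 64)
    neo_lvot_area(ph$mesh, ph$device, n_slices = 9)$min_area
  }, numeric(1))
  expect_true(all(diff(areas) < 0))

  # rigid rotation + translation of mesh and device together
  ph <- generate_3d_phantom(p, valve_frame_spec(diameter = 16, height = 12,
                                                protrusion_fraction = 0.5),
                            n_around = 64)
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  R2 <- rbind(c(1, 0, 0), c(0, cos(0.3), -sin(0.3)), c(0, sin(0.3), cos(0.3)))
  R <- R2 %*% R
  tr <- c(5, -3, 11)
  mesh_r <- ph$mesh
  mesh_r$vertices <- sweep(ph$mesh$vertices %*% t(R), 2, tr, "+")
  dev_r <- cylinder_device(ph$device$radius, ph$device$height,
                           as.numeric(R %*% ph$device$base_center) + tr,
                           as.numeric(R %*% ph$device$axis))
  a0 <- neo_lvot_area(ph$mesh, ph$device, n_slices = 9)
  a1 <- neo_lvot_area(mesh_r, dev_r, n_slices = 9)
  expect_equal(a1$profile$area_mm2, a0$profile$area_mm2, tolerance = 1e-6)
})

test_that("free-lumen areas agree with Monte-Carlo rejection sampling", {
  p <- lv_shape_params(lvot_width = 20, basal_diameter = 54)
  ph <- generate_3d_phantom(p, valve_frame_spec(diameter = 16, height = 12,
                                                protrusion_fraction = 0.6),
                            n_around = 96)
  res <- neo_lvot_area(ph$mesh, ph$device, n_slices = 5)
  # Monte-Carlo on the mid-device slice plane z = 8
  set.seed(7)
  n_mc <- 2e5
  pts2 <- cbind(runif(n_mc, -10, 10), runif(n_mc, -10, 10))
  in_tube <- rowSums(pts2^2) <= 100
  pts3 <- cbind(pts2, 8)
  in_dev <- vimflow:::points_in_cylinder(pts3, ph$device)
  frac <- mean(in_tube & !in_dev)
  mc_area <- frac * 400
  mc_se <- sqrt(frac * (1 - frac) / n_mc) * 400
  an_area <- pi * 100 - circle_lens_area(10, 8, 18 - 0.6 * 16)
  expect_lt(abs(mc_area - an_area), 3 * mc_se)
  expect_equal(res$min_area, an_area, tolerance = 0.005)
})

test_that("aortomitral angle follows the obtuse plane-line convention", {
  pl <- list(point = c(0, 0, 0), normal = c(0, 0, 1))
  expect_equal(aortomitral_angle(pl, c(1, 0, 0)), 180)     # axis in plane
  expect_equal(aortomitral_angle(pl, c(0, 0, 1)), 90)      # perpendicular
  expect_error(aortomitral_angle(pl, c(0, 0, 0)), "zero")
  # recover a phantom constructed at 113.2 degrees
  target <- 113.2
  phi <- (180 - target) * pi / 180
  axis <- c(cos(phi), 0, sin(phi))
  expect_equal(aortomitral_angle(pl, axis), target, tolerance = 0.5)
})

test_that("anatomic risk classes follow the clinical area rule", {
  expect_equal(classify_anatomic_risk(209.2), "acceptable")
  expect_equal(classify_anatomic_risk(180.0), "borderline")
  expect_equal(classify_anatomic_risk(200.0), "borderline")
  expect_equal(classify_anatomic_risk(100.0), "unacceptable")
  expect_equal(classify_anatomic_risk(179.999), "unacceptable")
  expect_equal(classify_anatomic_risk(200.001), "acceptable")
  expect_error(classify_anatomic_risk(-1), "non-negative")
})
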