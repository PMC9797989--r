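phantom_params <- function() lv_shape_params(lvot_width = 20, basal_diameter = 54)

test_that("tube phantom is watertight with analytic cross-sections", {
  ph <- generate_3d_phantom(phantom_params(),
                            valve_frame_spec(diameter = 16, height = 12,
                                             protrusion_fraction = 0),
                            n_around = 96)
  expect_true(mesh_is_watertight(ph$mesh))
  # device just touches from outside: every slice recovers pi r^2
  res <- neo_lvot_area(ph$mesh, ph$device, n_slices = 10)
  expect_equal(res$min_area, pi * 100, tolerance = 0.005)
  expect_equal(max(res$profile$area_mm2), pi * 100, tolerance = 0.005)
})

test_that("a device fully outside the tube leaves slice areas unchanged", {
  p <- phantom_params()
  ph <- generate_3d_phantom(p, valve_frame_spec(diameter = 16, height = 12,
                                                protrusion_fraction = 0),
                            n_around = 96)
  far <- cylinder_device(8, 12, base_center = c(60, 0, 2), axis = c(0, 0, 1))
  res0 <- neo_lvot_area(ph$mesh, far, n_slices = 8)
  res1 <- neo_lvot_area(ph$mesh, ph$device, n_slices = 8)
  expect_equal(res0$profile$area_mm2, res1$profile$area_mm2, tolerance = 1e-9)
})

test_that("overlapping device matches the closed-form lens area", {
  for (pf in c(0.3, 0.6, 0.9)) {
    ph <- generate_3d_phantom(phantom_params(),
                              valve_frame_spec(diameter = 16, height = 12,
                                               protrusion_fraction = pf),
                              n_around = 96)
    res <- neo_lvot_area(ph$mesh, ph$device, n_slices = 15)
    d <- (10 + 8) - pf * 16
    expected <- pi * 100 - circle_lens_area(10, 8, d)
    expect_equal(res$min_area, expected, tolerance = 0.005)
  }
})

test_that("STL export round-trips vertices and triangles", {
  ph <- generate_3d_phantom(phantom_params(), valve_frame_spec(),
                            n_around = 24, n_axial = 8)
  for (binary in c(TRUE, FALSE)) {
    path <- withr::local_tempfile(fileext = ".stl")
    lm <- withr::local_tempfile(fileext = ".json")
    write_stl(ph$mesh, path, binary = binary)
    write_mesh_landmarks(ph$mesh, lm)
    m2 <- read_stl(path, landmarks = lm)
    expect_equal(nrow(m2$triangles), nrow(ph$mesh$triangles))
    expect_true(mesh_is_watertight(m2))
    # same surface area
    area_of <- function(m) {
      v <- m$vertices; tr <- m$triangles
      s <- 0
      for (i in seq_len(nrow(tr))) {
        a <- v[tr[i, 2], ] - v[tr[i, 1], ]
        b <- v[tr[i, 3], ] - v[tr[i, 1], ]
        s <- s + 0.5 * sqrt(sum(c(a[2] * b[3] - a[3] * b[2],
                                  a[3] * b[1] - a[1] * b[3],
                                  a[1] * b[2] - a[2] * b[1])^2))
      }
      s
    }
    expect_equal(area_of(m2), area_of(ph$mesh), tolerance = 1e-5)
  }
})
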