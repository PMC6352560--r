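test_that("an isolated sphere recovers its closed-form area and unit ratio", {
  sys <- point_system(matrix(0, 1, 3), radius = 1.7)
  res <- surface_area(sys, n_sphere_points = 960)
  expect_equal(res$area_measured, 4 * pi * (1.7 + 1.4)^2, tolerance = 0.01)
  expect_equal(res$ratio, 1, tolerance = 0.01)
})

test_that("well-separated spheres contribute independent areas", {
  sys <- point_system(rbind(c(0, 0, 0), c(20, 0, 0)), radius = 1.7)
  res <- surface_area(sys, n_sphere_points = 960)
  expect_equal(res$area_measured, 2 * 4 * pi * (1.7 + 1.4)^2,
               tolerance = 0.01)
})

test_that("overlapping spheres match the closed-form union area", {
  for (d in c(2.0, 3.5, 5.0)) {
    sys <- point_system(rbind(c(0, 0, 0), c(d, 0, 0)), radius = 1.7)
    res <- surface_area(sys, n_sphere_points = 2000)
    expect_equal(res$area_measured, two_sphere_union_area(1.7, 1.7, d),
                 tolerance = 0.02)
  }
  # unequal radii
  sys <- point_system(rbind(c(0, 0, 0), c(3, 0, 0)), radius = 1.7)
  sys$particles$radius[2] <- 1.2
  res <- surface_area(sys, n_sphere_points = 2000)
  expect_equal(res$area_measured, two_sphere_union_area(1.7, 1.2, 3),
               tolerance = 0.02)
})

test_that("the estimate converges as sphere points increase", {
  sys <- point_system(rbind(c(0, 0, 0), c(3, 0, 0), c(1.5, 2.2, 0)),
                      radius = 1.7)
  dense <- surface_area(sys, n_sphere_points = 8000)$area_measured
  errs <- vapply(c(120, 480, 1920), function(np) {
    abs(surface_area(sys, n_sphere_points = np)$area_measured - dense)
  }, numeric(1))
  expect_lt(errs[3], errs[1])
  expect_lt(errs[3] / dense, 0.01)
})

test_that("missing radii are rejected and aspherical bodies give ratio > 1", {
  sys <- point_system(matrix(rnorm(30), 10, 3))
  sys$particles$radius[4] <- NA
  expect_error(surface_area(sys), "radius")
  rod <- point_system(cbind(seq(0, 30, by = 1.2), 0, 0), radius = 1.7)
  expect_gt(surface_area(rod, n_sphere_points = 480)$ratio, 1)
})
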