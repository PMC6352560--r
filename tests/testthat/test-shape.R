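test_that("radius of gyration matches symmetry cases and the two-pass sum", {
  expect_equal(radius_of_gyration(point_system(matrix(0, 1, 3))), 0)
  two <- point_system(rbind(c(-1, 0, 0), c(1, 0, 0)))
  expect_equal(radius_of_gyration(two), 1.0)
  set.seed(42)
  sys <- point_system(matrix(rnorm(300, sd = 5), 100, 3),
                      mass = runif(100, 1, 20))
  m <- sys$particles$mass
  com <- colSums(sys$coords * m) / sum(m)
  oracle <- sqrt(sum(m * rowSums(sweep(sys$coords, 2, com)^2)) / sum(m))
  expect_equal(radius_of_gyration(sys), oracle, tolerance = 1e-12)
})

test_that("eccentricity vanishes for cubic symmetry and matches the analytic ellipsoid", {
  cube <- as.matrix(expand.grid(c(-1, 1), c(-1, 1), c(-1, 1)))
  expect_equal(eccentricity(point_system(cube, mass = 1)), 0,
               tolerance = 1e-12)
  # lattice ball stretched along z: cubic-symmetric second moments make
  # the eccentricity exactly 1 - 3/(2 + s^2) for z-scale s > 1
  pts <- as.matrix(expand.grid(-8:8, -8:8, -8:8))
  pts <- pts[rowSums(pts^2) <= 64, ]
  for (s in c(1.2, 1.5, 2.0)) {
    sys <- point_system(pts %*% diag(c(1, 1, s)), mass = 1)
    expect_equal(eccentricity(sys), 1 - 3 / (2 + s^2), tolerance = 1e-12)
  }
})

test_that("degenerate collinear configurations are rejected", {
  line <- cbind(seq_len(10), 0, 0)
  expect_error(eccentricity(point_system(line)), "collinear")
  expect_error(eccentricity(point_system(matrix(0, 2, 3))), "at least 3")
})

test_that("shape descriptors are invariant under rigid motion and scale correctly", {
  set.seed(7)
  sys <- point_system(matrix(rnorm(240, sd = 8), 80, 3),
                      mass = runif(80, 1, 16))
  moved <- rigid_move(sys, seed = 3)
  expect_equal(radius_of_gyration(moved), radius_of_gyration(sys),
               tolerance = 1e-9)
  expect_equal(eccentricity(moved), eccentricity(sys), tolerance = 1e-9)
  # Rg scales linearly, eccentricity not at all
  scaled <- transform_system(sys, scale = 3.7)
  expect_equal(radius_of_gyration(scaled), 3.7 * radius_of_gyration(sys),
               tolerance = 1e-9)
  expect_equal(eccentricity(scaled), eccentricity(sys), tolerance = 1e-9)
  shp <- shape_descriptors(sys)
  expect_lte(shp$principal_moments[1], shp$i_average)
  expect_gte(shp$eccentricity, 0)
  expect_lt(shp$eccentricity, 1)
})

test_that("radial profiles recover a uniform ball and conserve mass", {
  set.seed(5)
  n <- 20000
  u <- matrix(rnorm(3 * n), n, 3)
  u <- u / sqrt(rowSums(u^2))
  r <- 40 * runif(n)^(1 / 3)
  sys <- point_system(u * r, mass = 2)
  prof <- radial_density_profile(sys, bin_width = 5)
  inner <- prof$density[prof$bin_mid < 35]
  expect_lt(stats::sd(inner) / mean(inner), 0.1)     # flat plateau
  expect_equal(sum(prof$shell_mass[prof$bin_edges[-1] > 46]), 0)
  expect_equal(sum(prof$shell_mass), total_mass(sys), tolerance = 1e-12)
  expect_error(radial_density_profile(sys, bin_width = 0), "positive")
})

test_that("an analytic two-step profile is recovered within binning error", {
  pre <- tiny_preset(40L)
  ch <- build_chain_topology(pre, seed = 2)
  dp <- c(core_density = 0.02, core_radius = 30, decay_radius = 60)
  cfg <- generator_config(seed = 19, n_chains = 400, preset = pre,
                          density_profile = dp)
  asm <- pack_assembly(ch, cfg)
  prof <- radial_density_profile(asm$system, bin_width = 5)
  # normalize to the core level: plateau flat, then a monotone decay to
  # zero near the nominal decay radius (chain extent smears the edges)
  got <- prof$density / mean(prof$density[prof$bin_mid < 25])
  # binning error: 5 A bins convolved with ~7 A chain extents
  plateau <- got[prof$bin_mid > 10 & prof$bin_mid < 25]
  expect_lt(max(abs(plateau - 1)), 0.25)
  tail_part <- got[prof$bin_mid > 35 & prof$bin_mid < 70]
  expect_true(all(diff(tail_part) < 0.05))
  expect_equal(sum(prof$shell_mass[prof$bin_edges[-1] > 72]), 0)
})
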