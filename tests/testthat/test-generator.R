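test_that("identical generator configs reproduce assemblies bitwise", {
  pre <- small_wdpu_preset()
  ch <- build_chain_topology(pre, seed = 4)
  cfg <- generator_config(seed = 21, n_chains = 5, preset = pre,
                          density_profile = c(core_density = 0.05,
                                              core_radius = 20,
                                              decay_radius = 45))
  a <- pack_assembly(ch, cfg)
  b <- pack_assembly(ch, cfg)
  expect_identical(a$system$coords, b$system$coords)
  expect_identical(a$ground_truth, b$ground_truth)
})

test_that("realized radial density integrates to the total mass", {
  pre <- small_wdpu_preset()
  ch <- build_chain_topology(pre, seed = 4)
  cfg <- generator_config(seed = 9, n_chains = 8, preset = pre,
                          density_profile = c(core_density = 0.05,
                                              core_radius = 25,
                                              decay_radius = 55))
  asm <- pack_assembly(ch, cfg)
  prof <- radial_density_profile(asm$system)
  integrated <- sum(prof$density *
                      (4 / 3) * pi * diff(prof$bin_edges^3))
  expect_equal(integrated, total_mass(asm$system), tolerance = 0.01)
})

test_that("flat isotropic packing of many short chains is nearly spherical", {
  pre <- tiny_preset(40L)
  ch <- build_chain_topology(pre, seed = 1)
  cfg <- generator_config(seed = 13, n_chains = 150, preset = pre,
                          persistence = 0,
                          density_profile = c(core_density = 0.03,
                                              core_radius = 40,
                                              decay_radius = 55))
  asm <- pack_assembly(ch, cfg)
  expect_lt(eccentricity(asm$system), 0.03)
  # plateau inside the core, zero past the decay radius (+ chain extent)
  prof <- radial_density_profile(asm$system, bin_width = 5)
  core <- prof$density[prof$bin_mid > 10 & prof$bin_mid < 35]
  expect_lt(stats::sd(core) / mean(core), 0.25)
  expect_equal(sum(prof$shell_mass[prof$bin_edges[-1] > 62]), 0)
})

test_that("anisotropy scale factors deform the assembly as requested", {
  pre <- tiny_preset(40L)
  ch <- build_chain_topology(pre, seed = 1)
  base <- generator_config(seed = 5, n_chains = 120, preset = pre,
                           density_profile = c(core_density = 0.03,
                                               core_radius = 30,
                                               decay_radius = 42))
  squash <- base; squash$anisotropy <- c(1, 1, 1.4)
  e0 <- eccentricity(pack_assembly(ch, base)$system)
  e1 <- eccentricity(pack_assembly(ch, squash)$system)
  expect_gt(e1, e0 + 0.05)
})

test_that("single-chain assemblies keep the sampled conformation shape", {
  pre <- tiny_preset(40L)
  ch <- build_chain_topology(pre, seed = 1)
  cfg <- generator_config(seed = 3, n_chains = 1, preset = pre,
                          density_profile = c(core_density = 0.01,
                                              core_radius = 10,
                                              decay_radius = 30))
  asm <- pack_assembly(ch, cfg)
  conf <- sample_chain_conformation(ch, persistence = cfg$persistence,
                                    seed = wdpunano:::child_seed(3, 1))
  # rigid placement: pairwise distances identical to the raw conformation
  d_asm <- dist(asm$system$coords[1:10, ])
  d_conf <- dist(conf[1:10, ])
  expect_equal(as.numeric(d_asm), as.numeric(d_conf), tolerance = 1e-9)
  expect_equal(end_to_end_distances(asm$system)$chain_mean,
               attr(conf, "end_to_end"))
})

test_that("physically infeasible target densities are rejected", {
  pre <- tiny_preset(40L)
  ch <- build_chain_topology(pre, seed = 1)
  cfg <- generator_config(seed = 2, n_chains = 500, preset = pre,
                          density_profile = c(core_density = 0.5,
                                              core_radius = 5,
                                              decay_radius = 12))
  expect_error(pack_assembly(ch, cfg), "infeasible density")
})

test_that("planted hydrogen bonds are recovered exactly, decoys never", {
  pre <- small_wdpu_preset()
  ch <- build_chain_topology(pre, seed = 6)
  cfg <- generator_config(seed = 31, n_chains = 6, preset = pre,
                          density_profile = c(core_density = 0.05,
                                              core_radius = 20,
                                              decay_radius = 45),
                          planted_hbonds = list(count = 10, d_DA = 2.8,
                                                angle = 10),
                          decoy_hbonds = list(count = 5, mode = "distance"))
  asm <- pack_assembly(ch, cfg)
  expect_identical(nrow(asm$ground_truth$planted_hbonds), 10L)
  expect_identical(nrow(asm$ground_truth$decoy_hbonds), 5L)
  det <- detect_hbonds(asm$system)
  truth_keys <- with(asm$ground_truth$planted_hbonds,
                     paste(donor_id, hydrogen_id, acceptor_id))
  det_keys <- with(det, paste(donor_id, hydrogen_id, acceptor_id))
  expect_setequal(det_keys, truth_keys)
  decoy_keys <- with(asm$ground_truth$decoy_hbonds,
                     paste(donor_id, hydrogen_id, acceptor_id))
  expect_length(intersect(det_keys, decoy_keys), 0)
})

test_that("planting zero bonds sterilizes all polar contacts", {
  pre <- small_wdpu_preset()
  ch <- build_chain_topology(pre, seed = 6)
  cfg <- generator_config(seed = 8, n_chains = 5, preset = pre,
                          density_profile = c(core_density = 0.05,
                                              core_radius = 18,
                                              decay_radius = 40),
                          planted_hbonds = list(count = 0, d_DA = 2.8,
                                                angle = 10),
                          decoy_hbonds = list(count = 1, mode = "angle"))
  asm <- pack_assembly(ch, cfg)
  expect_identical(nrow(detect_hbonds(asm$system)), 0L)
})

test_that("calibration hits reachable targets and rejects unreachable ones", {
  pre <- small_wdpu_preset()
  cfg <- generator_config(seed = 17, n_chains = 8, preset = pre,
                          density_profile = c(core_density = 0.05,
                                              core_radius = 20,
                                              decay_radius = 45))
  ch <- build_chain_topology(pre, seed = 17)
  nb <- sum(ch$particles$backbone) - 1L
  contour <- nb * cfg$bond_length
  # near-rigid-rod target lands near persistence 1
  cal <- calibrate_preset("mean_end_to_end", 0.99 * contour, cfg,
                          tolerance = 0.01)
  expect_gt(cal$persistence, 0.9)
  expect_equal(attr(cal, "achieved"), 0.99 * contour, tolerance = 0.01)
  # below the collapsed-globule floor: error reports the achievable range
  expect_error(calibrate_preset("mean_end_to_end", 0.1, cfg),
               "achievable")
  expect_error(calibrate_preset("mean_end_to_end", 2 * contour, cfg),
               "achievable")
})
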