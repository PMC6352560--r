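test_that("shipped presets fill soft-segment slots 6 PCL + 2 PLA", {
  for (name in c("PCL75DL25", "PCL75LL25")) {
    ch <- build_chain_topology(composition_preset(name), seed = 3)
    expect_identical(sum(ch$slot_types == "PCL"), 6L)
    expect_identical(sum(ch$slot_types == "PLA"), 2L)
    # every soft segment flanked by donor-role nitrogens
    mk <- ch$segment_markers[ch$segment_markers$scope == "segment", ]
    roles <- ch$particles$hbond_role[c(mk$start, mk$end)]
    expect_true(all(roles == "donor_heavy"))
  }
})

test_that("chain construction is reproducible for fixed preset and seed", {
  pre <- composition_preset("PCL75DL25")
  expect_identical(build_chain_topology(pre, seed = 11),
                   build_chain_topology(pre, seed = 11))
  # different seeds may relocate the PLA slots
  slots <- vapply(1:20, function(s) {
    paste(build_chain_topology(pre, seed = s)$slot_types, collapse = "")
  }, character(1))
  expect_gt(length(unique(slots)), 1L)
})

test_that("non-representable soft-segment fractions are rejected", {
  pre <- composition_preset("custom", pcl_fraction = 0.7)
  expect_error(build_chain_topology(pre, seed = 1), "not representable")
})

test_that("monomer particle counts and masses match hand-summed formulas", {
  mono <- default_monomers()
  # PCL repeat C6H10O2 with explicit hydrogens: 18 atoms, 114.14 Da
  pcl <- monomer_particles(mono$PCL, explicit_hydrogens = TRUE)
  expect_identical(nrow(pcl), 18L)
  expect_equal(sum(pcl$mass), 6 * 12.011 + 10 * 1.008 + 2 * 15.999,
               tolerance = 1e-6)
  expect_equal(sum(pcl$mass), 114.14, tolerance = 1e-3)
  # PLA repeat C3H4O2: 9 atoms, 72.06 Da
  pla <- monomer_particles(mono$PLA, explicit_hydrogens = TRUE)
  expect_identical(nrow(pla), 9L)
  expect_equal(sum(pla$mass), 72.06, tolerance = 1e-2)
  # united beads fold hydrogens into heavy atoms, same mass
  expect_equal(sum(monomer_particles(mono$PCL)$mass), sum(pcl$mass),
               tolerance = 1e-9)
})

test_that("default chains meet the per-chain particle-count target", {
  ch <- build_chain_topology(composition_preset("PCL75DL25"), seed = 1)
  n <- count_particles(ch)
  expect_identical(as.integer(n), 3070L)
  expect_equal(attr(n, "total_mass"), total_mass(ch))
  expect_gt(attr(n, "total_mass"), 0)
})

test_that("unit cells concatenate chains with unique ids", {
  ch <- build_chain_topology(composition_preset("PCL75DL25"), seed = 1)
  cell <- assemble_unit_cell(ch, 10)
  expect_identical(nrow(cell$particles), 30700L)
  expect_identical(length(unique(cell$particles$chain_id)), 10L)
  expect_identical(anyDuplicated(cell$particles$id), 0L)
  # single chain: identity on the particle table
  one <- assemble_unit_cell(ch, 1)
  expect_identical(nrow(one$particles), nrow(ch$particles))
  expect_error(assemble_unit_cell(list(), 0), "n_chains")
})

test_that("cell replication multiplies counts exactly and keeps labels", {
  ch <- build_chain_topology(composition_preset("PCL75DL25"), seed = 1)
  cell <- assemble_unit_cell(ch, 10)
  expect_error(replicate_cell(cell, 2, 2, 2), "bounding box")
  cell$box <- c(120, 120, 120)
  big <- replicate_cell(cell, 2, 2, 2)
  expect_identical(nrow(big$particles), 245600L)
  expect_identical(length(unique(big$particles$chain_id)), 80L)
  # composition invariant under replication
  frac <- function(s) {
    soft <- s$particles$segment_type != "HARD"
    mean(s$particles$segment_type[soft] == "PCL")
  }
  expect_equal(frac(big), frac(cell))
  # identity replication
  expect_identical(nrow(replicate_cell(cell, 1, 1, 1)$particles),
                   nrow(cell$particles))
})

test_that("a toy 3-particle cell replicates to enumerated coordinates", {
  sys <- point_system(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)))
  sys$box <- c(10, 10, 10)
  out <- replicate_cell(sys, 2, 1, 1)
  expect_identical(nrow(out$particles), 6L)
  expect_identical(length(unique(out$particles$chain_id)), 2L)
  expect_equal(out$coords[4:6, 1], sys$coords[, 1] + 10)
  expect_equal(out$coords[4:6, 2:3], sys$coords[, 2:3])
})
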