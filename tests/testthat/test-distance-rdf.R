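test_that("end-to-end distances respect straight-chain and contour bounds", {
  ch <- build_chain_topology(tiny_preset(60L), seed = 1)
  sys <- assemble_unit_cell(ch, 1)
  sys$coords <- unclass(sample_chain_conformation(ch, persistence = 1,
                                                  seed = 2))
  ee <- end_to_end_distances(sys)
  expect_equal(ee$chains$distance, ee$chains$contour, tolerance = 1e-9)
  for (s in 1:8) {
    sys$coords <- unclass(sample_chain_conformation(
      ch, persistence = runif(1, -0.5, 0.8), seed = s))
    ee <- end_to_end_distances(sys)
    expect_lte(ee$chains$distance, ee$chains$contour + 1e-9)
    expect_true(all(ee$segments$distance >= 0))
    expect_setequal(unique(ee$segments$segment_type), c("PCL", "PLA"))
  }
})

test_that("missing markers produce an error naming the chain", {
  sys <- point_system(matrix(rnorm(30), 10, 3))
  expect_error(end_to_end_distances(sys), "markers")
  ch <- build_chain_topology(tiny_preset(60L), seed = 1)
  sys2 <- assemble_unit_cell(ch, 2)
  sys2$coords <- matrix(rnorm(3 * nrow(sys2$particles)),
                        ncol = 3)
  sys2$segment_markers <- sys2$segment_markers[
    sys2$segment_markers$chain_id != 2L, ]
  expect_error(end_to_end_distances(sys2), "2")
})

test_that("two points fall into the single bin containing their distance", {
  res <- rdf(rbind(c(0, 0, 0), c(7.6, 0, 0)), bin_width = 0.5, r_max = 10)
  expect_identical(sum(res$raw_counts), 1L)
  expect_equal(res$bin_centers[res$raw_counts == 1L], 7.75)
  expect_equal(res$peak, 7.75)
  expect_error(rdf(matrix(rnorm(30), 10, 3), bin_width = 0.5, r_max = 0.4),
               "r_max")
})

test_that("uniform points in a sphere give near-unit g at short range", {
  set.seed(23)
  n <- 4000
  u <- matrix(rnorm(3 * n), n, 3)
  u <- u / sqrt(rowSums(u^2))
  pts <- u * 50 * runif(n)^(1 / 3)
  res <- rdf(pts, bin_width = 1, r_max = 60)
  short <- res$bin_centers > 2 & res$bin_centers < 6
  expect_equal(mean(res$g[short]), 1, tolerance = 0.1)
  # raw counts conserve the pair count within r_max
  d <- as.numeric(dist(pts))
  expect_identical(sum(res$raw_counts), sum(d <= res$r_max))
})

test_that("lattice spacings appear as RDF peak bin centers", {
  g <- as.matrix(expand.grid(0:4, 0:4, 0:4))
  res <- rdf(g * 17.75, bin_width = 0.5)
  expect_equal(res$peak, 17.75)
  res2 <- rdf(g * 8.25, bin_width = 0.5)
  expect_equal(res2$peak, 8.25)
  expect_equal(res2$first_peak, 8.25)
})

test_that("cross RDFs count every ordered pair once", {
  set.seed(4)
  a <- matrix(runif(30, 0, 10), 10, 3)
  b <- matrix(runif(60, 0, 10), 20, 3)
  res <- rdf(a, b, bin_width = 1, r_max = 25)
  expect_identical(sum(res$raw_counts), 200L)
})

test_that("segment and chain centroids feed the RDF machinery", {
  pre <- small_wdpu_preset()
  ch <- build_chain_topology(pre, seed = 3)
  cfg <- generator_config(seed = 3, n_chains = 8, preset = pre,
                          density_profile = c(core_density = 0.05,
                                              core_radius = 20,
                                              decay_radius = 45))
  asm <- pack_assembly(ch, cfg)
  cc <- chain_centroids(asm$system)
  expect_identical(dim(cc), c(8L, 3L))
  sp <- segment_centroids(asm$system, "PLA")
  expect_identical(nrow(sp), 8L)  # 1 PLA slot per 4-slot chain x 8 chains
  res <- rdf(cc, bin_width = 0.5)
  expect_s3_class(res, "rdf_result")
  expect_gte(min(res$g), 0)
})
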